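# Independent brute-force oracles used to validate the vectorized and
# compiled implementations. These are deliberately naive (loops, direct
# definitions) and share no code with the package internals.

# Mirror-reflected index (edge-inclusive), matching the package's stated
# border convention.
oracle_reflect <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  ifelse(i > n, 2 * n - i + 1, i)
}

# Flat grayscale dilation/erosion by explicit window max/min over the mask
# (windows truncated at the array edge; no padding here).
oracle_morph <- function(f, mask, radius, op = c("dilate", "erode")) {
  op <- match.arg(op)
  h <- nrow(f); w <- ncol(f)
  off <- which(mask == 1, arr.ind = TRUE) - (radius + 1L)
  out <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    ri <- off[, 1] + i; ci <- off[, 2] + j
    keep <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- f[cbind(ri[keep], ci[keep])]
    out[i, j] <- if (op == "dilate") max(v) else min(v)
  }
  out
}

# Closing/opening on the mirror-padded (by 2*radius) domain, cropped back —
# the package's stated border convention.
oracle_closing <- function(f, mask, radius) {
  r2 <- 2L * radius
  h <- nrow(f); w <- ncol(f)
  fp <- f[oracle_reflect(seq(1 - r2, h + r2), h),
          oracle_reflect(seq(1 - r2, w + r2), w)]
  e <- oracle_morph(oracle_morph(fp, mask, radius, "dilate"),
                    mask, radius, "erode")
  e[r2 + seq_len(h), r2 + seq_len(w)]
}

oracle_opening <- function(f, mask, radius) {
  r2 <- 2L * radius
  h <- nrow(f); w <- ncol(f)
  fp <- f[oracle_reflect(seq(1 - r2, h + r2), h),
          oracle_reflect(seq(1 - r2, w + r2), w)]
  d <- oracle_morph(oracle_morph(fp, mask, radius, "erode"),
                    mask, radius, "dilate")
  d[r2 + seq_len(h), r2 + seq_len(w)]
}

# Per-pixel scalar re-implementation of the local-energy fusion rule.
oracle_fuse_lf <- function(LC, LD, Wc = matrix(1, 3, 3), T = 0.5,
                           amin = 0.3, amax = 0.7) {
  h <- nrow(LC); w <- ncol(LC)
  out <- matrix(0, h, w)
  wsum <- function(L1, L2, x, y) {
    s <- 0
    for (m in -1:1) for (n in -1:1) {
      xi <- oracle_reflect(x + m, h); yi <- oracle_reflect(y + n, w)
      s <- s + Wc[m + 2, n + 2] * L1[xi, yi] * L2[xi, yi]
    }
    s
  }
  for (x in 1:h) for (y in 1:w) {
    eC <- wsum(LC, LC, x, y); eD <- wsum(LD, LD, x, y)
    S <- if (eC + eD < 1e-12) 1 else 2 * wsum(LC, LD, x, y) / (eC + eD)
    if (S > T) {
      aC <- if (eC >= eD) amax else amin
      out[x, y] <- aC * LC[x, y] + (1 - aC) * LD[x, y]
    } else {
      out[x, y] <- if (eC >= eD) LC[x, y] else LD[x, y]
    }
  }
  out
}

# Naive loop guided filter with border-truncated box means.
oracle_guided <- function(p, I, r, eps) {
  h <- nrow(I); w <- ncol(I)
  bm <- function(x) {
    out <- matrix(0, h, w)
    for (i in 1:h) for (j in 1:w)
      out[i, j] <- mean(x[max(1, i - r):min(h, i + r),
                          max(1, j - r):min(w, j + r)])
    out
  }
  mI <- bm(I); mp <- bm(p)
  a <- (bm(I * p) - mI * mp) / (bm(I * I) - mI^2 + eps)
  b <- mp - a * mI
  pmin(pmax(bm(a) * I + bm(b), 0), 1)
}

# Truncated-window border box mean (loop version) for the guided-filter
# large-regularization limit.
oracle_box_mean <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w)
    out[i, j] <- mean(x[max(1, i - r):min(h, i + r),
                        max(1, j - r):min(w, j + r)])
  out
}

# Majority vote over the truncated 8x8 window (extra rows/cols toward lower
# indices); ties keep the original value.
oracle_majority <- function(B, window = 8L) {
  h <- nrow(B); w <- ncol(B)
  lo <- window %/% 2L; hi <- window - lo - 1L
  out <- B
  for (i in 1:h) for (j in 1:w) {
    win <- B[max(1, i - lo):min(h, i + hi), max(1, j - lo):min(w, j + hi)]
    n1 <- sum(win); n0 <- length(win) - n1
    out[i, j] <- if (n1 > n0) 1 else if (n0 > n1) 0 else B[i, j]
  }
  out
}

# Circular shift of a matrix.
circ_shift <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dr) %% h) + 1, ((seq_len(w) - 1 - dc) %% w) + 1]
}

# Variance of the 4-neighbor Laplacian (focus measure).
lap_var <- function(m) {
  h <- nrow(m); w <- ncol(m)
  k <- -4 * m[2:(h - 1), 2:(w - 1)] + m[1:(h - 2), 2:(w - 1)] +
    m[3:h, 2:(w - 1)] + m[2:(h - 1), 1:(w - 2)] + m[2:(h - 1), 3:w]
  stats::var(as.vector(k))
}
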