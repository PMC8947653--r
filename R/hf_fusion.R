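# High-pass sub-band fusion: dense clarity scoring by the trained Siamese
# classifier, choose-max thresholding, 8x8 majority-vote consistency
# verification, guided-filter refinement and convex compositing.

#' Dense clarity score map for a band pair
#'
#' Both bands are affinely normalized to \[0, 1\] (x -> (x - min)/(max - min +
#' 1e-12)) and pushed through the fully-convolutional shared branch; each
#' output unit is the soft-max probability that the first band's 16x16
#' receptive-field block is the clearer one. Block scores (stride 2) are
#' redistributed to pixel resolution by accumulating every score over its
#' 16x16 source block and dividing by the per-pixel coverage count, yielding
#' a map `M` of the input size with values in \[0, 1\].
#'
#' @param weights trained `network_weights`.
#' @param Ch,Dh numeric matrices of identical shape, dims >= 16.
#' @return score map `M`, same size as the inputs.
#' @export
feature_detect <- function(weights, Ch, Dh) {
  if (!inherits(weights, "network_weights"))
    stop("weights must be network_weights", call. = FALSE)
  assert_image(Ch, "Ch"); assert_image(Dh, "Dh")
  assert_same_shape(Ch, Dh, "bands")
  H <- nrow(Ch); W <- ncol(Ch)
  if (H < 16 || W < 16) stop("dims must be >= 16", call. = FALSE)

  norm01 <- function(x) (x - min(x)) / (max(x) - min(x) + 1e-12)
  x <- array(c(norm01(Ch), norm01(Dh)), dim = c(H, W, 2L, 1L))
  br <- branch_fwd(x, weights)
  P <- dim(br$feat)[1]; Q <- dim(br$feat)[2]
  nf <- dim(br$feat)[4]
  f1 <- matrix(br$feat[, , 1L, ], P * Q, nf)
  f2 <- matrix(br$feat[, , 2L, ], P * Q, nf)
  logits <- sweep(cbind(f1, f2) %*% weights$head$W, 2, weights$head$b, `+`)
  s <- matrix(softmax_rows(logits)[, 2L], P, Q)

  # each unit (i, j) summarizes the 16x16 block starting at (2i-1, 2j-1)
  M <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (i in seq_len(P)) {
    ri <- (2L * i - 1L):(2L * i + 14L)
    for (j in seq_len(Q)) {
      ci <- (2L * j - 1L):(2L * j + 14L)
      M[ri, ci] <- M[ri, ci] + s[i, j]
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
  }
  covered <- cnt > 0
  M[covered] <- M[covered] / cnt[covered]
  if (!all(covered)) {           # thin uncovered border on odd-sized inputs
    rmax <- max(which(rowSums(covered) > 0))
    cmax <- max(which(colSums(covered) > 0))
    if (rmax < H) M[(rmax + 1):H, ] <- M[rep(rmax, H - rmax), ]
    if (cmax < W) M[, (cmax + 1):W] <- M[, rep(cmax, W - cmax)]
  }
  M
}

#' Threshold a score map into a binary map
#'
#' Choose-max selection: `B = 1` where `M > 0.5` (strictly), else 0.
#'
#' @param M score map with values in \[0, 1\].
#' @return binary matrix of the same size.
#' @export
initial_segment <- function(M) {
  assert_image(M, "M")
  if (min(M) < 0 || max(M) > 1)
    stop("M values must lie in [0, 1]", call. = FALSE)
  (M > 0.5) * 1
}

#' Remove isolated misclassifications by sliding majority vote
#'
#' Each pixel is replaced by the majority value of its 8x8 neighborhood
#' (window offset convention: the extra rows/columns of the even-sized window
#' extend toward lower indices, i.e. rows `i-4 .. i+3`). The window is
#' truncated at image borders; an exact tie keeps the original pixel.
#'
#' @param B binary matrix (values 0/1 only).
#' @param window window side length (default 8).
#' @return binary matrix of the same size.
#' @export
consistency_verify <- function(B, window = 8L) {
  assert_image(B, "B")
  if (!all(B %in% c(0, 1))) stop("B must be binary", call. = FALSE)
  h <- nrow(B); w <- ncol(B)
  lo <- window %/% 2L; hi <- window - lo - 1L   # 4 before, 3 after

  # integral image with zero padding; truncated-window counts
  S <- rbind(0, apply(B, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  r1 <- pmax(seq_len(h) - lo, 1L); r2 <- pmin(seq_len(h) + hi, h)
  c1 <- pmax(seq_len(w) - lo, 1L); c2 <- pmin(seq_len(w) + hi, w)
  ones <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  size <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  out <- (ones > size / 2) * 1
  tie <- ones == size / 2
  out[tie] <- B[tie]
  out
}

# Box mean with border-truncated windows (integral-image implementation).
box_mean <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  S <- rbind(0, apply(x, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(w) - r, 1L); c2 <- pmin(seq_len(w) + r, w)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  sums / outer(r2 - r1 + 1L, c2 - c1 + 1L)
}

#' Guided-filter refinement of a verified binary map
#'
#' Standard guided image filter (local linear model q = a*I + b fitted per
#' window, coefficients averaged) with window radius `r` and regularization
#' `eps`; the guide is the preprocessed source image, whose edges the refined
#' decision map inherits. Output is clipped to \[0, 1\].
#'
#' @param B_v verified binary (or \[0, 1\]) map.
#' @param guide guide image in \[0, 1\], same shape.
#' @param r window radius in pixels.
#' @param eps regularization of the linear-model variance.
#' @return decision map `Dm` in \[0, 1\].
#' @export
refine_decision <- function(B_v, guide, r = 4L, eps = 0.1) {
  assert_image(B_v, "B_v"); assert_image(guide, "guide")
  assert_same_shape(B_v, guide, "map and guide")
  mI <- box_mean(guide, r)
  mp <- box_mean(B_v, r)
  corrIp <- box_mean(guide * B_v, r)
  varI <- box_mean(guide * guide, r) - mI^2
  a <- (corrIp - mI * mp) / (varI + eps)
  b <- mp - a * mI
  clip01(box_mean(a, r) * guide + box_mean(b, r))
}

#' Convex compositing of a high-pass band pair
#'
#' `Fh = Dm * Ch + (1 - Dm) * Dh` on the raw (un-normalized) coefficients.
#'
#' @param Dm decision map in \[0, 1\].
#' @param Ch,Dh band matrices, same shape as `Dm`.
#' @return fused band.
#' @export
fuse_hf <- function(Dm, Ch, Dh) {
  assert_image(Dm, "Dm"); assert_image(Ch, "Ch"); assert_image(Dh, "Dh")
  assert_same_shape(Dm, Ch, "Dm and Ch")
  assert_same_shape(Ch, Dh, "bands")
  if (min(Dm) < 0 || max(Dm) > 1)
    stop("Dm values must lie in [0, 1]", call. = FALSE)
  Dm * Ch + (1 - Dm) * Dh
}
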