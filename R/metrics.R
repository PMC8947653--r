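# Objective fusion-quality metrics: edge-information transfer (QFAB),
# source-fused correlation (CRR), average gradient (AG), and the fused-edge
# artifact/noise measure (NFAB). QFAB and NFAB follow the Xydeas-Petrovic
# edge-preservation framework: per-pixel Sobel strength/orientation, sigmoid
# preservation scores, edge-strength weighting. The sigmoids are normalized
# so that a perfectly preserved edge scores exactly 1.

sobel_gradients <- function(x) {
  xp <- pad_symmetric(x, 1L)
  h <- nrow(x); w <- ncol(x)
  sh <- function(dr, dc) xp[dr + seq_len(h), dc + seq_len(w)]
  gx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) -
        (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  gy <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) -
        (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  g <- sqrt(gx^2 + gy^2)
  a <- atan2(gy, gx)                       # wrap to (-pi/2, pi/2]
  a[a > pi / 2] <- a[a > pi / 2] - pi
  a[a <= -pi / 2] <- a[a <= -pi / 2] + pi
  a[g == 0] <- 0
  list(g = g, a = a)
}

# Per-pixel edge preservation Q^{XF} of source X in fused F.
edge_preservation <- function(sx, sf, kg, sg, ka, sa) {
  G <- matrix(1, nrow(sx$g), ncol(sx$g))
  nz <- (sx$g > 0) | (sf$g > 0)
  G[nz] <- pmin(sx$g, sf$g)[nz] / pmax(sx$g, sf$g)[nz]
  da <- abs(sx$a - sf$a)
  da <- pmin(da, pi - da)                   # orientation distance in [0, pi/2]
  A <- 1 - da / (pi / 2)
  Qg <- (1 + exp(kg * (1 - sg))) / (1 + exp(kg * (G - sg)))
  Qa <- (1 + exp(ka * (1 - sa))) / (1 + exp(ka * (A - sa)))
  Qg * Qa
}

metric_check <- function(A, B, F) {
  assert_image(A, "A"); assert_image(B, "B"); assert_image(F, "F")
  assert_same_shape(A, B, "sources")
  assert_same_shape(A, F, "source and fused")
}

#' Edge-transfer quality QFAB
#'
#' Xydeas-Petrovic edge-information transfer from sources `A`, `B` to the
#' fused image `F`: per-pixel sigmoid scores of relative Sobel edge strength
#' and orientation preservation, weighted by source edge strength.
#' 1 means perfect transfer; constants are exposed for variant definitions.
#'
#' @param A,B source images; `F` fused image (same shape).
#' @param kg,sg strength-sigmoid slope and offset.
#' @param ka,sa orientation-sigmoid slope and offset.
#' @return scalar in \[0, 1\].
#' @export
qfab <- function(A, B, F, kg = -10, sg = 0.5, ka = -20, sa = 0.75) {
  metric_check(A, B, F)
  sa_ <- sobel_gradients(A); sb <- sobel_gradients(B); sf <- sobel_gradients(F)
  QA <- edge_preservation(sa_, sf, kg, sg, ka, sa)
  QB <- edge_preservation(sb, sf, kg, sg, ka, sa)
  wA <- sa_$g; wB <- sb$g
  tot <- sum(wA + wB)
  if (tot <= 0) stop("both sources are constant: QFAB undefined", call. = FALSE)
  sum(QA * wA + QB * wB) / tot
}

#' Fusion artifact (noise) measure NFAB
#'
#' Fraction of weighted fused-edge information at artifact locations: pixels
#' where the fused edge is strictly stronger than both source edges
#' contribute their unpreserved information `wA*(1-Q^AF) + wB*(1-Q^BF)`.
#' 0 means every fused edge has a source counterpart; lower is better.
#'
#' @inheritParams qfab
#' @return scalar in \[0, 1\].
#' @export
nfab <- function(A, B, F, kg = -10, sg = 0.5, ka = -20, sa = 0.75) {
  metric_check(A, B, F)
  sa_ <- sobel_gradients(A); sb <- sobel_gradients(B); sf <- sobel_gradients(F)
  QA <- edge_preservation(sa_, sf, kg, sg, ka, sa)
  QB <- edge_preservation(sb, sf, kg, sg, ka, sa)
  wA <- sa_$g; wB <- sb$g
  tot <- sum(wA + wB)
  if (tot <= 0) stop("both sources are constant: NFAB undefined", call. = FALSE)
  AM <- (sf$g > sa_$g) & (sf$g > sb$g)
  sum(AM * (wA * (1 - QA) + wB * (1 - QB))) / tot
}

#' Mean source-fused correlation CRR
#'
#' Mean of the Pearson correlations `cor(A, F)` and `cor(B, F)`.
#'
#' @inheritParams qfab
#' @return scalar in \[-1, 1\].
#' @export
crr <- function(A, B, F) {
  metric_check(A, B, F)
  if (stats::sd(A) == 0 || stats::sd(B) == 0 || stats::sd(F) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  (stats::cor(as.vector(A), as.vector(F)) +
     stats::cor(as.vector(B), as.vector(F))) / 2
}

#' Average gradient AG
#'
#' Mean over interior pixels of `sqrt((dx^2 + dy^2)/2)` with forward
#' differences; a sharpness measure, 0 for constant images.
#'
#' @param F image matrix with dims >= 2.
#' @return nonnegative scalar.
#' @export
avg_gradient <- function(F) {
  assert_image(F, "F", min_dim = 2)
  h <- nrow(F); w <- ncol(F)
  dx <- F[seq_len(h - 1), 2:w, drop = FALSE] - F[seq_len(h - 1), seq_len(w - 1), drop = FALSE]
  dy <- F[2:h, seq_len(w - 1), drop = FALSE] - F[seq_len(h - 1), seq_len(w - 1), drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' All four fusion metrics at once
#'
#' @inheritParams qfab
#' @return list with elements `qfab`, `crr`, `ag`, `nfab`.
#' @export
fusion_metrics <- function(A, B, F) {
  list(qfab = qfab(A, B, F), crr = crr(A, B, F),
       ag = avg_gradient(F), nfab = nfab(A, B, F))
}
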