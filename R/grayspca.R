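# PCA-based decolorization.
#
# RGB inputs are mapped to YCbCr (ITU-R BT.601, full range), each channel is
# zero-meaned, and a PCA over the 3-vector pixel population yields an
# orthonormal basis ordered by explained variance. The gray image is the
# combination of the three projections weighted by sqrt(lambda_k) (normalized),
# so the dominant luminance-like component carries most weight while the
# chroma components restore residual detail. Eigenvector signs are fixed by
# positive correlation with luminance so the output is deterministic.

ycbcr_from_rgb <- function(img) {
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  Y  <- 0.299 * R + 0.587 * G + 0.114 * B
  Cb <- 0.5 - 0.168736 * R - 0.331264 * G + 0.5 * B
  Cr <- 0.5 + 0.5 * R - 0.418688 * G - 0.081312 * B
  list(Y = Y, Cb = Cb, Cr = Cr)
}

#' PCA decolorization of an RGB image
#'
#' @param img numeric array `h x w x 3` with values in \[0, 1\].
#' @return gray matrix in \[0, 1\] (min-max rescaled). If the input has zero
#'   chroma variance (R=G=B) the result equals the rescaled common channel;
#'   a fully constant image is returned as its constant luminance.
#' @export
decolorize <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L))
    stop("img must be an h x w x 3 array", call. = FALSE)
  if (any(!is.finite(img))) stop("img contains non-finite values", call. = FALSE)

  ch <- ycbcr_from_rgb(img)
  X <- cbind(as.vector(ch$Y), as.vector(ch$Cb), as.vector(ch$Cr))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2) / nrow(Xc)
  if (total_var < 1e-12) {                      # constant image fallback
    return(matrix(mu[1], nrow(img), ncol(img)))
  }
  S <- crossprod(Xc) / nrow(Xc)
  e <- eigen(S, symmetric = TRUE)               # eigenvalues sorted descending
  lam <- pmax(e$values, 0)
  V <- e$vectors
  # orthonormality contract of the basis
  stopifnot(max(abs(crossprod(V) - diag(3))) < 1e-8)

  proj <- Xc %*% V                              # three projection images
  yv <- Xc[, 1]
  for (k in 1:3) {                              # deterministic sign fix
    s <- sum(proj[, k] * yv)
    if (abs(s) < 1e-12) s <- V[which.max(abs(V[, k])), k]
    if (s < 0) { V[, k] <- -V[, k]; proj[, k] <- -proj[, k] }
  }
  w <- sqrt(lam)
  w <- w / sum(w)
  g <- as.vector(proj %*% w)
  rescale01(matrix(g, nrow(img), ncol(img)))
}

#' Convert any supported input to a gray image
#'
#' Gray matrices pass through unchanged (idempotent); 3-channel arrays are
#' decolorized via [decolorize()]. Any other channel count is an error.
#'
#' @param img numeric matrix or `h x w x 3` array.
#' @return gray matrix in \[0, 1\].
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) {
    assert_image(img)
    return(img)
  }
  if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) return(img[, , 1])
    if (dim(img)[3] == 3L) return(decolorize(img))
  }
  stop("channel count must be 1 or 3", call. = FALSE)
}
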