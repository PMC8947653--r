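# Internal helpers shared across modules.

#' Clamp values to the unit interval
#' @param x numeric vector, matrix or array.
#' @return `x` with every value clamped to \[0, 1\].
#' @keywords internal
#' @noRd
clip01 <- function(x) pmin(pmax(x, 0), 1)

# Affine min-max rescale to [0,1]; constant inputs map to 0.
rescale01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite values in image", call. = FALSE)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    return(array(0, dim = dim(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Mirror (edge-inclusive symmetric) padding by `r` pixels on every side.
pad_symmetric <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  if (r >= h || r >= w) stop("padding exceeds image size", call. = FALSE)
  ri <- c(r:1, 1:h, h:(h - r + 1))
  ci <- c(r:1, 1:w, w:(w - r + 1))
  x[ri, ci, drop = FALSE]
}

# Reflected index vector for out-of-range neighbor access (0 -> 2 below,
# n+1 -> n above); internal convention of the generator's Gaussian blur.
reflect_index <- function(i, n) {
  i <- ifelse(i < 1, 1 - i + 1, i)
  ifelse(i > n, 2 * n - i + 1, i)
}

assert_image <- function(x, name = "image", min_dim = 1) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("%s contains non-finite values", name), call. = FALSE)
  if (nrow(x) < min_dim || ncol(x) < min_dim)
    stop(sprintf("%s must be at least %dx%d", name, min_dim, min_dim), call. = FALSE)
  invisible(x)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions", what), call. = FALSE)
  invisible(NULL)
}

# Separable Gaussian blur with mirror padding (used by the synthetic generator).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  r <- min(r, nrow(x) - 1L, ncol(x) - 1L)  # truncate on tiny images
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(x); w <- ncol(x)
  # rows
  xp <- x[reflect_index(seq(1 - r, h + r), h), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * xp[j:(j + h - 1), , drop = FALSE]
  # cols
  xp <- out[, reflect_index(seq(1 - r, w + r), w), drop = FALSE]
  out2 <- matrix(0, h, w)
  for (j in seq_along(k)) out2 <- out2 + k[j] * xp[, j:(j + w - 1), drop = FALSE]
  out2
}

#' Peak signal-to-noise ratio between two unit-range images
#'
#' @param x,y numeric matrices on a \[0, 1\] intensity scale.
#' @return PSNR in decibels (`Inf` for identical images).
#' @export
psnr <- function(x, y) {
  assert_same_shape(x, y)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}
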