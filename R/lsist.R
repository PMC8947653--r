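# Local shift-invariant shearlet transform (LSIST).
#
# Two stages, both undecimated so every band has the input's size:
#
#   1. Multiscale split by non-subsampled pyramid filters: an a-trous pyramid
#      built from the B3-spline low-pass whose per-axis frequency response is
#      H(w) = ((1 + cos w)/2)^2, dilated by 2^(s-1) at scale s. The high-pass
#      analysis spectrum is K = sqrt(1 - H^2), which makes the pyramid a tight
#      frame: |F_s|^2 = |F_{s+1}|^2 + |G_s|^2 pointwise, so band energies sum
#      exactly to the image energy and synthesis is self-adjoint
#      (F_s = H F_{s+1} + K G_s), giving machine-precision reconstruction.
#
#   2. Directional localization: each high-pass band is multiplied in the DFT
#      domain by Meyer-window wedge filters defined on the pseudo-polar grid
#      (slope coordinate eta = xi2/xi1 on the horizontal cone, 2 - xi1/xi2 on
#      the vertical cone, period 4) and resampled on the Cartesian DFT grid.
#      The squared windows sum to 1 at every nonzero frequency, so the adjoint
#      (multiply again and sum over directions) inverts the stage exactly.
#
# All filtering is pointwise in the DFT domain, hence periodic boundaries and
# exact equivariance under circular shifts. Filter banks are cached per
# (height, width, scales, directions).

.lsist_cache <- new.env(parent = emptyenv())

fft2 <- function(x) stats::fft(x)
ifft2 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

# DFT frequencies in cycles/sample, in [-1/2, 1/2)
dft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n) / n
}

# Meyer auxiliary polynomial (0 at 0, 1 at 1, C^3 joins)
meyer_nu <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# Meyer bump: b(0)=1, support (-1,1), sum_j b(u-j)^2 = 1
meyer_bump <- function(u) {
  a <- pmin(abs(u), 1)
  ifelse(abs(u) < 1, cos(pi / 2 * meyer_nu(a)), 0)
}

# Per-axis B3-spline a-trous low-pass spectrum at dilation d
atrous_lowpass_1d <- function(n, d) {
  w <- 2 * pi * dft_freq(n) * d
  ((1 + cos(w)) / 2)^2
}

validate_directions <- function(directions_per_scale, scales) {
  d <- as.integer(directions_per_scale)
  if (length(d) == 1L) d <- rep(d, scales)
  if (length(d) != scales)
    stop("directions_per_scale must have one count per scale", call. = FALSE)
  if (any(d < 2L) || any(bitwAnd(d, d - 1L) != 0L))
    stop("each direction count must be a power of 2, >= 2", call. = FALSE)
  d
}

#' Build the directional shearing filter bank
#'
#' Meyer-window wedge filters on the pseudo-polar slope grid, sampled on the
#' Cartesian DFT grid of the given size. Per scale, the squared magnitudes of
#' the direction windows sum to 1 at every frequency (the DC sample is
#' assigned wholly to the first wedge), which is verified at build time.
#'
#' @param height,width band dimensions in pixels (>= 8).
#' @param scales number of scales S (>= 1).
#' @param directions_per_scale integer vector of direction counts D_s, each a
#'   power of 2 (a single value is recycled over scales).
#' @return object of class `shear_filter_bank`: list with `windows` (per
#'   scale, a list of D_s real `height x width` spectra), `height`, `width`,
#'   `scales`, `directions_per_scale`.
#' @export
build_shear_filter_bank <- function(height, width, scales = 3,
                                    directions_per_scale = c(8, 8, 16)) {
  if (height < 8 || width < 8) stop("dims must be >= 8", call. = FALSE)
  if (scales < 1) stop("scales must be >= 1", call. = FALSE)
  dirs <- validate_directions(directions_per_scale, scales)

  f1 <- matrix(dft_freq(height), height, width)               # row frequency
  f2 <- matrix(dft_freq(width), height, width, byrow = TRUE)  # col frequency
  horiz <- abs(f1) >= abs(f2)
  eta <- matrix(0, height, width)
  nz1 <- horiz & (f1 != 0)
  eta[nz1] <- f2[nz1] / f1[nz1]
  nzv <- !horiz
  eta[nzv] <- 2 - f1[nzv] / f2[nzv]
  dc <- (f1 == 0) & (f2 == 0)

  # Hermitian pairing k -> (n - k) mod n per axis. Windows must be invariant
  # under it so taking the real part of filtered bands commutes with the
  # adjoint; the slope coordinate already is, except on the Nyquist row and
  # column of even-sized grids, where each window is symmetrized and the
  # partition of unity renormalized (identity everywhere else).
  p1 <- c(1L, rev(seq_len(height - 1) + 1L))
  p2 <- c(1L, rev(seq_len(width - 1) + 1L))

  windows <- vector("list", scales)
  for (s in seq_len(scales)) {
    D <- dirs[s]
    ws <- vector("list", D)
    for (d in seq_len(D)) {
      eta_d <- 4 * (d - 1) / D
      delta <- ((eta - eta_d + 2) %% 4) - 2
      W <- meyer_bump(delta * D / 4)
      W[dc] <- if (d == 1L) 1 else 0
      ws[[d]] <- (W + W[p1, p2]) / 2
    }
    pou <- Reduce(`+`, lapply(ws, function(w) w^2))
    ws <- lapply(ws, function(w) w / sqrt(pou))
    pou <- Reduce(`+`, lapply(ws, function(w) w^2))
    if (max(abs(pou - 1)) > 1e-6)
      stop("filter bank does not partition unity", call. = FALSE)
    windows[[s]] <- ws
  }
  structure(list(windows = windows, height = height, width = width,
                 scales = scales, directions_per_scale = dirs),
            class = "shear_filter_bank")
}

# Cached pyramid (H_s, K_s) spectra + shear bank for a configuration
lsist_filters <- function(height, width, scales, dirs) {
  key <- paste(height, width, scales, paste(dirs, collapse = "."), sep = "_")
  if (!is.null(.lsist_cache[[key]])) return(.lsist_cache[[key]])
  H <- vector("list", scales)
  K <- vector("list", scales)
  for (s in seq_len(scales)) {
    d <- 2^(s - 1)
    Hs <- outer(atrous_lowpass_1d(height, d), atrous_lowpass_1d(width, d))
    H[[s]] <- Hs
    K[[s]] <- sqrt(pmax(0, 1 - Hs^2))
  }
  bank <- build_shear_filter_bank(height, width, scales, dirs)
  .lsist_cache[[key]] <- list(H = H, K = K, bank = bank)
  .lsist_cache[[key]]
}

#' Decompose an image into an undecimated shearlet pyramid
#'
#' @param img numeric matrix; dimensions must be at least `2^scales` and >= 8.
#' @param scales number of scales S (>= 1).
#' @param directions_per_scale direction counts per scale, each a power of 2.
#' @return object of class `subband_pyramid`: list with `low` (matrix),
#'   `high` (list over scales of lists over directions of matrices),
#'   `scales`, `directions_per_scale`.
#' @export
lsist_decompose <- function(img, scales = 3, directions_per_scale = c(8, 8, 16)) {
  assert_image(img, "img", min_dim = 8)
  if (min(dim(img)) < 2^scales)
    stop("image dims must be >= 2^scales", call. = FALSE)
  dirs <- validate_directions(directions_per_scale, scales)
  flt <- lsist_filters(nrow(img), ncol(img), scales, dirs)

  Fs <- fft2(img)
  high <- vector("list", scales)
  for (s in seq_len(scales)) {
    G <- Fs * flt$K[[s]]
    Fs <- Fs * flt$H[[s]]
    high[[s]] <- lapply(flt$bank$windows[[s]],
                        function(W) Re(ifft2(W * G)))
  }
  structure(list(low = Re(ifft2(Fs)), high = high, scales = scales,
                 directions_per_scale = dirs),
            class = "subband_pyramid")
}

#' Reconstruct an image from a shearlet pyramid
#'
#' Directional bands are recombined through the adjoint Meyer windows into
#' each scale's high-pass band, then the tight-frame pyramid synthesis folds
#' the scales back onto the low band. Output is real-valued and not clipped.
#'
#' @param pyr a `subband_pyramid` from [lsist_decompose()] (bands may have
#'   been modified, e.g. by fusion).
#' @return numeric matrix of the original size.
#' @export
lsist_reconstruct <- function(pyr) {
  if (!inherits(pyr, "subband_pyramid")) stop("not a subband_pyramid", call. = FALSE)
  h <- nrow(pyr$low); w <- ncol(pyr$low)
  for (s in seq_len(pyr$scales)) {
    if (length(pyr$high[[s]]) != pyr$directions_per_scale[s])
      stop("direction count mismatch", call. = FALSE)
    for (band in pyr$high[[s]])
      if (!identical(dim(band), c(h, w)))
        stop("mismatched band shapes", call. = FALSE)
  }
  flt <- lsist_filters(h, w, pyr$scales, pyr$directions_per_scale)
  Fs <- fft2(pyr$low)
  for (s in rev(seq_len(pyr$scales))) {
    Ws <- flt$bank$windows[[s]]
    G <- matrix(0 + 0i, h, w)
    for (d in seq_along(Ws)) G <- G + Ws[[d]] * fft2(pyr$high[[s]][[d]])
    Fs <- Fs * flt$H[[s]] + flt$K[[s]] * G
  }
  Re(ifft2(Fs))
}
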