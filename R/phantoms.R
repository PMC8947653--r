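# Synthetic co-registered CT-like / MRI-like phantom pairs and labeled
# sharp/blurred patch pairs. Every downstream stage of the fusion pipeline is
# testable offline against these generators; they are first-class package code,
# not test fixtures.

#' Smooth multiplicative illumination field
#'
#' A low-order polynomial ramp `1 + strength * (0.6*(u - 1/2) + 0.4*(v - 1/2))`
#' where `u, v` are the column/row coordinates normalized to \[0, 1\]. Because
#' both coordinate grids average exactly 1/2, the analytic mean of the field
#' over the image is exactly 1 for any size and strength.
#'
#' @param size image side length in pixels.
#' @param strength ramp amplitude in \[0, 1); 0 gives a flat field.
#' @return `size` x `size` matrix of multiplicative gains.
#' @export
illumination_field <- function(size, strength) {
  stopifnot(size >= 2, strength >= 0, strength < 1)
  u <- matrix((seq_len(size) - 1) / (size - 1), size, size, byrow = TRUE)
  v <- matrix((seq_len(size) - 1) / (size - 1), size, size)
  1 + strength * (0.6 * (u - 0.5) + 0.4 * (v - 0.5))
}

#' Generate a co-registered CT-like / MRI-like phantom pair
#'
#' Produces two single-slice head phantoms sharing identical anatomy: an
#' elliptical "skull" ring plus 3--5 interior soft-tissue blobs. The CT-like
#' image shows the ring bright (bone) over a dark interior with faint blob
#' contrast; the MRI-like image shows the ring dark and a bright, textured
#' soft-tissue interior (band-limited Gaussian texture, correlation length
#' 2.5 px). Both are corrupted by additive Gaussian noise of standard
#' deviation `noise_sd`, multiplied by a smooth illumination ramp of amplitude
#' `illum_strength` (mirror-imaged between the two modalities), and clipped to
#' \[0, 1\]. Output is a pure function of the arguments.
#'
#' @param size side length in pixels (>= 64).
#' @param noise_sd additive Gaussian noise standard deviation (intensity units).
#' @param illum_strength illumination ramp amplitude in \[0, 1).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return An object of class `phantom_pair`: a list with matrices `ct` and
#'   `mri` in \[0, 1\], logical anatomy masks `ring_mask` and `interior_mask`
#'   (identical for both modalities), and the generation parameters.
#' @export
generate_phantom_pair <- function(size = 128, noise_sd = 0.02,
                                  illum_strength = 0.3, seed = 1) {
  if (size < 64) stop("size must be >= 64", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (illum_strength < 0 || illum_strength >= 1)
    stop("illum_strength must be in [0, 1)", call. = FALSE)

  with_seed(seed, {
    u <- matrix((seq_len(size) - 1) / (size - 1), size, size, byrow = TRUE)
    v <- matrix((seq_len(size) - 1) / (size - 1), size, size)
    # elliptical radius: rho = 1 on the skull mid-line
    rho <- sqrt(((u - 0.5) / 0.38)^2 + ((v - 0.5) / 0.34)^2)

    ring_w <- 0.09                       # ring half-width in rho units
    ring <- exp(-((rho - 1) / ring_w)^2) # smooth bone profile
    inside <- 1 / (1 + exp((rho - (1 - 2 * ring_w)) / 0.02))  # soft indicator

    # 3-5 shared soft-tissue blobs inside the skull
    n_blob <- sample(3:5, 1)
    blobs <- matrix(0, size, size)
    for (i in seq_len(n_blob)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.55)
      bx <- 0.5 + 0.38 * rad * cos(ang)
      by <- 0.5 + 0.34 * rad * sin(ang)
      bs <- runif(1, 0.04, 0.10)
      blobs <- blobs + runif(1, 0.6, 1) * exp(-(((u - bx)^2 + (v - by)^2) / (2 * bs^2)))
    }
    blobs <- pmin(blobs, 1)

    # band-limited MRI texture, correlation length ~2.5 px
    tex <- gaussian_blur(matrix(stats::rnorm(size * size), size, size), 2.5)
    tex <- tex / stats::sd(tex)

    ct  <- 0.12 + 0.78 * ring + inside * (0.18 + 0.18 * blobs)
    mri <- 0.10 + inside * (0.45 + 0.22 * blobs + 0.12 * tex) - 0.06 * ring

    illum <- illumination_field(size, illum_strength)
    ct  <- clip01(ct * illum + stats::rnorm(size * size, 0, noise_sd))
    mri <- clip01(mri * illum[, size:1] + stats::rnorm(size * size, 0, noise_sd))

    structure(list(
      ct = ct, mri = mri,
      ring_mask = abs(rho - 1) <= ring_w,
      interior_mask = rho <= 1 - 3 * ring_w,
      size = size, noise_sd = noise_sd,
      illum_strength = illum_strength, seed = seed
    ), class = "phantom_pair")
  })
}

#' Generate labeled sharp/blurred patch pairs for classifier training
#'
#' Each pair is a textured random patch and a Gaussian-blurred copy of it
#' (blur standard deviation drawn uniformly from `blur_sd_range`), presented
#' in random order. `label` is 1 when `patch_a` holds the sharp member and 0
#' otherwise; the order is decided by a fair coin per pair so labels balance.
#' This corpus stands in for the (undescribed) training data of the
#' sharp-versus-blurred patch classifier used in high-pass fusion.
#'
#' @param n number of pairs (>= 2).
#' @param patch_size square patch side in pixels (>= 8).
#' @param blur_sd_range length-2 numeric, min/max blur sigma in pixels.
#' @param seed integer RNG seed.
#' @return An object of class `patch_pair_set`: list with arrays `patch_a`,
#'   `patch_b` of dim `(patch_size, patch_size, n)`, integer vector `label`,
#'   and `patch_size`.
#' @export
generate_patch_pairs <- function(n, patch_size = 16, blur_sd_range = c(1, 3),
                                 seed = 1) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (patch_size < 8) stop("patch_size must be >= 8", call. = FALSE)
  if (length(blur_sd_range) != 2 || diff(blur_sd_range) < 0 ||
      blur_sd_range[1] <= 0)
    stop("blur_sd_range must be a nonempty positive interval", call. = FALSE)

  with_seed(seed, {
    ps <- patch_size
    a <- array(0, dim = c(ps, ps, n))
    b <- array(0, dim = c(ps, ps, n))
    label <- integer(n)
    uu <- matrix((seq_len(ps) - 1) / (ps - 1), ps, ps, byrow = TRUE)
    vv <- matrix((seq_len(ps) - 1) / (ps - 1), ps, ps)
    for (i in seq_len(n)) {
      # textured content: fine smoothed noise + a random oriented edge
      sharp <- gaussian_blur(matrix(stats::rnorm(ps * ps), ps, ps),
                             stats::runif(1, 0.4, 0.8))
      th <- stats::runif(1, 0, pi)
      edge <- tanh((cos(th) * (uu - stats::runif(1, 0.3, 0.7)) +
                    sin(th) * (vv - stats::runif(1, 0.3, 0.7))) * 12)
      sharp <- 0.5 + 0.28 * edge + stats::runif(1, 0.1, 0.25) * sharp / stats::sd(sharp)
      sharp <- clip01(sharp)
      blur <- gaussian_blur(sharp, stats::runif(1, blur_sd_range[1], blur_sd_range[2]))
      if (stats::runif(1) < 0.5) {
        a[, , i] <- sharp; b[, , i] <- blur; label[i] <- 1L
      } else {
        a[, , i] <- blur; b[, , i] <- sharp; label[i] <- 0L
      }
    }
    structure(list(patch_a = a, patch_b = b, label = label, patch_size = ps),
              class = "patch_pair_set")
  })
}
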