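# Low-pass sub-band fusion by windowed local energy with a salience-gated
# averaging/selection rule. All windows are the 3x3 template Wc with
# mirror-padded borders.

#' Configuration of the local-energy fusion rule
#'
#' @param template 3x3 nonnegative weight matrix Wc (default all ones;
#'   normalization cancels in the salience ratio and energy comparisons).
#' @param threshold salience threshold T in (0, 1) separating averaging
#'   (S > T) from selection (S <= T).
#' @param alpha_min,alpha_max averaging weights for the lower/higher energy
#'   band; must satisfy `alpha_min + alpha_max = 1`.
#' @return object of class `energy_config`.
#' @export
energy_config <- function(template = matrix(1, 3, 3), threshold = 0.5,
                          alpha_min = 0.3, alpha_max = 0.7) {
  if (!is.matrix(template) || !identical(dim(template), c(3L, 3L)) ||
      any(template < 0))
    stop("template must be a nonnegative 3x3 matrix", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (abs(alpha_min + alpha_max - 1) > 1e-12)
    stop("alpha_min + alpha_max must equal 1", call. = FALSE)
  if (alpha_min < 0 || alpha_min > 0.5 || alpha_max < 0.5 || alpha_max > 1)
    stop("alpha_min in [0, 0.5], alpha_max in [0.5, 1]", call. = FALSE)
  structure(list(template = template, threshold = threshold,
                 alpha_min = alpha_min, alpha_max = alpha_max),
            class = "energy_config")
}

# Windowed weighted sum of `x` over the 3x3 template, mirror-padded.
window_sum <- function(x, Wc) {
  h <- nrow(x); w <- ncol(x)
  xp <- pad_symmetric(x, 1L)
  out <- matrix(0, h, w)
  for (m in 0:2) for (n in 0:2) {
    if (Wc[m + 1, n + 1] == 0) next
    out <- out + Wc[m + 1, n + 1] * xp[m + seq_len(h), n + seq_len(w)]
  }
  out
}

#' Local energy of a low-pass band
#'
#' `En(x, y) = sum_{m,n} L(x+m, y+n)^2 * Wc(m, n)` over the 3x3 window,
#' mirror-padded at borders; nonnegative everywhere.
#'
#' @param L band matrix, at least 3x3.
#' @param cfg an [energy_config()].
#' @return energy map of the same size.
#' @export
local_energy <- function(L, cfg = energy_config()) {
  assert_image(L, "L", min_dim = 3)
  window_sum(L^2, cfg$template)
}

#' Salience (match) factor of two low-pass bands
#'
#' `S = 2 * sum Wc * LC * LD / (EnC + EnD)` with the same window and weights
#' as [local_energy()]. Where both energies vanish (below 1e-12) the bands
#' are identically null and S is defined as 1. S lies in \[-1, 1\].
#'
#' @param LC,LD band matrices of identical shape.
#' @param EnC,EnD their energy maps (recomputed if omitted).
#' @param cfg an [energy_config()].
#' @return salience map of the same size.
#' @export
salience <- function(LC, LD, EnC = NULL, EnD = NULL, cfg = energy_config()) {
  assert_image(LC, "LC", min_dim = 3); assert_image(LD, "LD", min_dim = 3)
  assert_same_shape(LC, LD, "bands")
  if (is.null(EnC)) EnC <- local_energy(LC, cfg)
  if (is.null(EnD)) EnD <- local_energy(LD, cfg)
  assert_same_shape(LC, EnC, "band and energy map")
  assert_same_shape(LC, EnD, "band and energy map")
  num <- 2 * window_sum(LC * LD, cfg$template)
  den <- EnC + EnD
  S <- matrix(1, nrow(LC), ncol(LC))
  ok <- den >= 1e-12
  S[ok] <- num[ok] / den[ok]
  S
}

#' Fuse two low-pass bands by salience-gated averaging/selection
#'
#' Per pixel: if `S > T`, averaging mode `alphaC*LC + alphaD*LD` where
#' `alphaC = alpha_max` when `EnC >= EnD` (else `alpha_min`) and
#' `alphaD = 1 - alphaC`; if `S <= T`, selection of the higher-energy band's
#' coefficient (ties go to the first input).
#'
#' @param LC,LD band matrices of identical shape (>= 3x3).
#' @param cfg an [energy_config()].
#' @return fused band of the same size.
#' @export
fuse_lf <- function(LC, LD, cfg = energy_config()) {
  if (!inherits(cfg, "energy_config")) stop("cfg must be an energy_config", call. = FALSE)
  assert_image(LC, "LC", min_dim = 3); assert_image(LD, "LD", min_dim = 3)
  assert_same_shape(LC, LD, "bands")
  EnC <- local_energy(LC, cfg)
  EnD <- local_energy(LD, cfg)
  S <- salience(LC, LD, EnC, EnD, cfg)
  c_wins <- EnC >= EnD
  alphaC <- ifelse(c_wins, cfg$alpha_max, cfg$alpha_min)
  averaged <- alphaC * LC + (1 - alphaC) * LD
  selected <- ifelse(c_wins, LC, LD)
  ifelse(S > cfg$threshold, averaged, selected)
}
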