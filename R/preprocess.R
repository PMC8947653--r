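# Morphological bottom-hat / top-hat preprocessing.
#
# Medical inputs carry non-uniform background illumination and noise; the
# bottom-hat residue (closing - f) isolates dark artifacts while the top-hat
# residue (f - opening) isolates bright detail. Combining the two residues
# with the image flattens the background and boosts contrast before
# decomposition. Grayscale morphology is flat (min/max over a structuring
# element) and is delegated to EBImage; borders are handled by mirror-padding
# the image by twice the element radius so no spurious border residues appear
# on clipped anatomy.

#' Flat structuring element
#'
#' @param shape `"disk"` or `"square"`.
#' @param radius element radius in pixels (>= 1); the mask is
#'   `(2*radius+1)` x `(2*radius+1)`.
#' @return An object of class `struct_elem` with fields `mask` (0/1 matrix,
#'   symmetric under 180 degree rotation, origin at center), `shape`, `radius`.
#' @export
struct_elem <- function(shape = c("disk", "square"), radius = 9) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  side <- 2L * radius + 1L
  mask <- if (shape == "square") {
    matrix(1, side, side)
  } else {
    d <- outer((-radius):radius, (-radius):radius,
               function(i, j) sqrt(i^2 + j^2))
    (d <= radius) * 1
  }
  stopifnot(identical(mask, mask[side:1, side:1]))  # 180-degree symmetry
  structure(list(mask = mask, shape = shape, radius = radius),
            class = "struct_elem")
}

check_se <- function(f, b) {
  if (!inherits(b, "struct_elem")) stop("b must be a struct_elem", call. = FALSE)
  assert_image(f, "f")
  if (2L * b$radius + 1L > min(dim(f)))
    stop("structuring element larger than image", call. = FALSE)
}

# Grayscale opening/closing with mirror-padded borders.
morph_open_close <- function(f, b, op = c("open", "close")) {
  op <- match.arg(op)
  r <- b$radius
  fp <- pad_symmetric(f, 2L * r)
  out <- if (op == "close") {
    EBImage::erode(EBImage::dilate(fp, b$mask), b$mask)
  } else {
    EBImage::dilate(EBImage::erode(fp, b$mask), b$mask)
  }
  n <- 2L * r
  out[(n + 1):(n + nrow(f)), (n + 1):(n + ncol(f)), drop = FALSE]
}

#' Bottom-hat (closing residue)
#'
#' `closing(f, b) - f`; nonnegative, highlights dark pits and background
#' noise smaller than the structuring element.
#'
#' @param f numeric matrix in \[0, 1\].
#' @param b a [struct_elem()].
#' @return nonnegative residue matrix of the same size.
#' @export
bottom_hat <- function(f, b) {
  check_se(f, b)
  pmax(morph_open_close(f, b, "close") - f, 0)
}

#' Top-hat (opening residue)
#'
#' `f - opening(f, b)`; nonnegative, highlights bright peaks smaller than the
#' structuring element. Invariant to adding a constant to `f`.
#'
#' @inheritParams bottom_hat
#' @return nonnegative residue matrix of the same size.
#' @export
top_hat <- function(f, b) {
  check_se(f, b)
  pmax(f - morph_open_close(f, b, "open"), 0)
}

#' Morphological contrast enhancement
#'
#' Default (`variant = "classic"`) returns
#' `clip(f + top_hat(f, b) - bottom_hat(f, b), 0, 1)`: bright features are
#' boosted, dark artifacts suppressed, and slowly varying illumination (scale
#' larger than `b`) cancels between the two residues. The
#' `"paper_literal"` variant returns `clip(top_hat - bottom_hat, 0, 1)`,
#' i.e. the bare difference of residues without the image term.
#'
#' @inheritParams bottom_hat
#' @param variant `"classic"` (default) or `"paper_literal"`.
#' @return enhanced image in \[0, 1\].
#' @export
enhance <- function(f, b, variant = c("classic", "paper_literal")) {
  variant <- match.arg(variant)
  if (is.array(f) && length(dim(f)) == 3L) {  # per-channel on color inputs
    out <- f
    for (k in seq_len(dim(f)[3])) out[, , k] <- enhance(f[, , k], b, variant)
    return(out)
  }
  check_se(f, b)
  th <- top_hat(f, b)
  bh <- bottom_hat(f, b)
  if (variant == "classic") clip01(f + th - bh) else clip01(th - bh)
}

# Default element radius for a given image size: 9 px at 256 px, scaled
# proportionally, never below 3. Must exceed the noise/texture scale but stay
# below anatomy scale.
default_se_radius <- function(size) max(3L, as.integer(round(9 * size / 256)))
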