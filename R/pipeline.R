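# End-to-end fusion pipeline: preprocess -> decolorize -> shearlet
# decomposition -> per-band high-pass fusion + low-pass energy fusion ->
# inverse transform -> display normalization, plus quality metrics.

#' Full pipeline configuration
#'
#' All stated method constants default to their canonical values (segment
#' threshold 0.5, consistency window 8, 16x16 scoring blocks via the network
#' architecture, guided filter r = 4 and eps = 0.1, 3x3 energy template,
#' salience threshold T = 0.5).
#'
#' @param preprocess list: `shape` ("disk"/"square"), `radius` (0 = auto,
#'   scaled to image size: 9 px at 256), `variant`
#'   ("classic"/"paper_literal").
#' @param grayspca list: `enabled` (TRUE = auto-decolorize RGB inputs).
#' @param lsist list: `scales`, `directions` (counts per scale).
#' @param hf list: `map_scope` ("per_band" or "per_scale"), `guided_r`,
#'   `guided_eps`, `segment_threshold`, `consistency_window`.
#' @param lf an [energy_config()] or a list of its arguments.
#' @param output list: `normalize` ("minmax" or "clip").
#' @param seed integer, echoed into outputs for provenance.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(preprocess = list(), grayspca = list(),
                          lsist = list(), hf = list(), lf = list(),
                          output = list(), seed = 1L) {
  merge_defaults <- function(user, defaults) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    preprocess = merge_defaults(preprocess,
      list(shape = "disk", radius = 0L, variant = "classic")),
    grayspca = merge_defaults(grayspca, list(enabled = TRUE)),
    lsist = merge_defaults(lsist,
      list(scales = 3L, directions = c(8L, 8L, 16L))),
    hf = merge_defaults(hf,
      list(map_scope = "per_band", guided_r = 4L, guided_eps = 0.1,
           segment_threshold = 0.5, consistency_window = 8L)),
    lf = if (inherits(lf, "energy_config")) lf else do.call(energy_config, lf),
    output = merge_defaults(output, list(normalize = "minmax")),
    seed = as.integer(seed)
  )
  stopifnot(cfg$hf$map_scope %in% c("per_band", "per_scale"),
            cfg$output$normalize %in% c("minmax", "clip"))
  structure(cfg, class = "fusion_config")
}

#' Serialize / restore a fusion configuration as YAML
#'
#' @param cfg a [fusion_config()].
#' @param path YAML file path.
#' @return `read_fusion_config` returns the restored `fusion_config`.
#' @export
write_fusion_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fusion_config"))
  x <- unclass(cfg)
  x$lf <- list(template = as.vector(x$lf$template),
               threshold = x$lf$threshold,
               alpha_min = x$lf$alpha_min, alpha_max = x$lf$alpha_max)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_fusion_config
#' @export
read_fusion_config <- function(path) {
  x <- yaml::read_yaml(path)
  lf <- x$lf
  lf$template <- matrix(unlist(lf$template), 3, 3)
  fusion_config(preprocess = x$preprocess, grayspca = x$grayspca,
                lsist = x$lsist, hf = x$hf, lf = do.call(energy_config, lf),
                output = x$output, seed = x$seed)
}

# Preprocess one input: morphological enhancement then gray conversion.
preprocess_input <- function(img, cfg) {
  size <- if (is.matrix(img)) min(dim(img)) else min(dim(img)[1:2])
  radius <- cfg$preprocess$radius
  if (is.null(radius) || radius == 0) radius <- default_se_radius(size)
  se <- struct_elem(cfg$preprocess$shape, radius)
  enhanced <- enhance(img, se, cfg$preprocess$variant)
  if (is.matrix(enhanced)) return(enhanced)
  if (isTRUE(cfg$grayspca$enabled)) to_gray(enhanced)
  else ycbcr_from_rgb(enhanced)$Y          # plain luminance when PCA disabled
}

#' Fuse a co-registered image pair
#'
#' Both inputs are morphologically enhanced and reduced to gray, decomposed
#' by the undecimated shearlet transform, fused band-by-band (Siamese-CNN
#' decision maps for every high-pass pair, local-energy rule for the low-pass
#' pair), inversely transformed and normalized to \[0, 1\]. Metrics are
#' computed against the preprocessed sources (the images fusion actually
#' consumed). Deterministic given the configuration and weights.
#'
#' @param imgA,imgB gray matrices or RGB arrays of identical spatial size.
#' @param weights trained `network_weights` for the clarity classifier.
#' @param cfg a [fusion_config()].
#' @return list with `fused` (matrix in \[0, 1\]), `metrics`
#'   (list `qfab`/`crr`/`ag`/`nfab`), `sources` (preprocessed gray pair),
#'   and `config`.
#' @export
fuse_images <- function(imgA, imgB, weights, cfg = fusion_config()) {
  if (!inherits(cfg, "fusion_config")) stop("cfg must be a fusion_config", call. = FALSE)
  if (missing(weights) || !inherits(weights, "network_weights"))
    stop("trained network weights are required", call. = FALSE)
  dA <- if (is.matrix(imgA)) dim(imgA) else dim(imgA)[1:2]
  dB <- if (is.matrix(imgB)) dim(imgB) else dim(imgB)[1:2]
  if (!identical(dA, dB)) stop("input dimensions differ", call. = FALSE)

  A <- preprocess_input(imgA, cfg)
  B <- preprocess_input(imgB, cfg)

  pa <- lsist_decompose(A, cfg$lsist$scales, cfg$lsist$directions)
  pb <- lsist_decompose(B, cfg$lsist$scales, cfg$lsist$directions)

  fused <- pa
  for (s in seq_len(pa$scales)) {
    nd <- pa$directions_per_scale[s]
    if (cfg$hf$map_scope == "per_scale") {
      Ms <- lapply(seq_len(nd), function(d)
        feature_detect(weights, pa$high[[s]][[d]], pb$high[[s]][[d]]))
      M <- Reduce(`+`, Ms) / nd
      Dm <- refine_decision(
        consistency_verify((M > cfg$hf$segment_threshold) * 1,
                           cfg$hf$consistency_window),
        A, cfg$hf$guided_r, cfg$hf$guided_eps)
      for (d in seq_len(nd))
        fused$high[[s]][[d]] <- fuse_hf(Dm, pa$high[[s]][[d]], pb$high[[s]][[d]])
    } else {
      for (d in seq_len(nd)) {
        M <- feature_detect(weights, pa$high[[s]][[d]], pb$high[[s]][[d]])
        B_map <- (M > cfg$hf$segment_threshold) * 1
        Dm <- refine_decision(consistency_verify(B_map, cfg$hf$consistency_window),
                              A, cfg$hf$guided_r, cfg$hf$guided_eps)
        fused$high[[s]][[d]] <- fuse_hf(Dm, pa$high[[s]][[d]], pb$high[[s]][[d]])
      }
    }
  }
  fused$low <- fuse_lf(pa$low, pb$low, cfg$lf)

  out <- lsist_reconstruct(fused)
  out <- if (cfg$output$normalize == "minmax") rescale01(out) else clip01(out)

  list(fused = out, metrics = fusion_metrics(A, B, out),
       sources = list(A = A, B = B), config = cfg)
}

#' Read an image file as \[0, 1\] intensities
#'
#' PNG and TIFF, 8/16-bit gray or RGB; an alpha channel is dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return matrix (gray) or `h x w x 3` array (RGB).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
       else stop("unsupported image format: ", path, call. = FALSE)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 4L) x <- x[, , 1:3]
    if (dim(x)[3] == 2L) x <- x[, , 1]
    if (!is.matrix(x) && dim(x)[3] == 1L) x <- x[, , 1]
  }
  x
}

#' Write an image to PNG (8-bit) or TIFF (32-bit float)
#'
#' @param img matrix or array in \[0, 1\].
#' @param path output path; the extension selects the format.
#' @return the path, invisibly.
#' @export
write_image <- function(img, path) {
  img <- clip01(img)
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(img, path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(img, path, bits.per.sample = 32L)
  else stop("unsupported image format: ", path, call. = FALSE)
  invisible(path)
}
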