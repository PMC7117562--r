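#' Convert pixel intensities to optical density
#'
#' Per pixel, `od = -10 * log10(max(pixel, epsilon * white_level) /
#' white_level)`: the Feulgen densitometry convention of ten times the
#' decadic absorbance, so a pixel at one tenth of the blank reference has
#' OD 10. Dark pixels are clamped at `epsilon * white_level` to keep OD
#' finite; a pixel at `white_level` has OD exactly 0, and OD is strictly
#' decreasing in intensity on `[epsilon * white_level, white_level]`.
#'
#' @param image an [image_plane] (or plain matrix with `white_level` given).
#' @param white_level blank reference. `NULL` (default) uses the image's own
#'   `white_level` attribute (bit-depth maximum unless overridden);
#'   `"background"` estimates it as the modal image intensity, appropriate
#'   when the slide background is the brightest common level; a number uses
#'   that value.
#' @param epsilon clamp fraction in (0, 1); default `1e-4` caps OD at 40.
#' @return Numeric matrix of class `od_map` with attribute `white_level`.
#' @export
to_optical_density <- function(image, white_level = NULL, epsilon = 1e-4) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  wl <- resolve_white_level(image, white_level)
  px <- pmax(unclass(image), epsilon * wl)
  od <- -10 * log10(px / wl)
  od[od < 0] <- 0  # pixels brighter than the reference carry no stain
  structure(od, white_level = wl, class = "od_map")
}

# Modal intensity via tabulation; the background dominates a sparse slide.
resolve_white_level <- function(image, white_level) {
  if (is.null(white_level)) {
    wl <- attr(image, "white_level")
    if (is.null(wl)) stop("no white_level on image; pass one explicitly")
    return(wl)
  }
  if (identical(white_level, "background")) {
    tab <- tabulate(as.integer(unclass(image)) + 1L)
    return(which.max(tab) - 1)
  }
  if (identical(white_level, "max")) {
    bd <- attr(image, "bit_depth")
    if (is.null(bd)) stop("image has no bit_depth; pass a numeric white_level")
    return(2^bd - 1)
  }
  wl <- as.numeric(white_level)
  if (is.na(wl) || wl <= 0) stop("white_level must be positive")
  wl
}

#' Integrate optical density over one nucleus
#'
#' The IOD is the sum of per-pixel OD over exactly the ROI's rasterized
#' pixel set; it is additive over disjoint pixel subsets and untouched by
#' any pixel outside the ROI.
#'
#' @param od_map matrix from [to_optical_density()].
#' @param roi a [nucleus_roi].
#' @param min_area smallest acceptable rasterized area in pixels
#'   (default 10); degenerate delineations are rejected.
#' @return One-row data.frame: `roi_id, cell_class, area_px, iod, mean_od`.
#' @export
integrated_optical_density <- function(od_map, roi, min_area = 10L) {
  shape <- dim(od_map)
  px <- rasterize_roi(roi, shape)
  if (nrow(px) == 0L) stop("ROI ", roi$id, " rasterizes to no pixels")
  if (!is.null(roi$polygon)) {
    if (min(roi$polygon[, 2]) < 0 || max(roi$polygon[, 2]) > shape[1] ||
        min(roi$polygon[, 1]) < 0 || max(roi$polygon[, 1]) > shape[2])
      stop("ROI ", roi$id, " extends outside the image")
  }
  if (nrow(px) < min_area)
    stop("ROI ", roi$id, " area ", nrow(px), " px below min_area ", min_area)
  iod <- sum(od_map[px[, 1] + 1L + px[, 2] * shape[1]])
  data.frame(roi_id = roi$id, cell_class = roi$cell_class,
             area_px = nrow(px), iod = iod, mean_od = iod / nrow(px),
             stringsAsFactors = FALSE)
}

#' Measure every nucleus in a sample
#'
#' Runs the OD transform once and integrates it over each ROI. The protocol
#' expects 30 lymphocyte controls and 150-200 epithelial cells per sample;
#' counts outside those bands raise warnings, and a sample with no control
#' nuclei is an error because DI normalization is then impossible.
#'
#' @param image an [image_plane].
#' @param rois list of [nucleus_roi].
#' @param white_level,epsilon passed to [to_optical_density()].
#' @param min_area passed to [integrated_optical_density()].
#' @param overlap `"error"` (default) or `"warn"`: overlapping ROIs violate
#'   the nonoverlap protocol but field exports occasionally contain slips.
#' @return data.frame with one row per ROI:
#'   `roi_id, cell_class, area_px, iod, mean_od`.
#' @export
measure_sample <- function(image, rois, white_level = NULL, epsilon = 1e-4,
                           min_area = 10L, overlap = c("error", "warn")) {
  overlap <- match.arg(overlap)
  if (length(rois) == 0L) stop("no ROIs to measure")
  chk <- check_nonoverlap(rois, dim(image))
  if (!chk$ok) {
    msg <- sprintf("%d pixel(s) shared by overlapping ROIs (%s)",
                   chk$n_shared_pixels,
                   paste(utils::head(paste(chk$pairs$roi_a, chk$pairs$roi_b,
                                           sep = "/"), 5L), collapse = ", "))
    if (overlap == "error") stop(msg) else warning(msg)
  }
  classes <- vapply(rois, `[[`, "", "cell_class")
  n_ctrl <- sum(classes == "control")
  n_epi <- sum(classes == "epithelial")
  if (n_ctrl == 0L) stop("no control ROIs: DI normalization impossible")
  if (n_ctrl < 30L)
    warning(sprintf("only %d control nuclei (protocol expects 30)", n_ctrl))
  if (n_epi < 150L || n_epi > 200L)
    warning(sprintf("%d epithelial nuclei (protocol expects 150-200)", n_epi))
  od <- to_optical_density(image, white_level = white_level, epsilon = epsilon)
  out <- do.call(rbind, lapply(rois, integrated_optical_density,
                               od_map = od, min_area = min_area))
  rownames(out) <- NULL
  out
}
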