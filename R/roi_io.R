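#' Image plane
#'
#' A single-channel 2-D intensity raster, the densitometry substrate. Pixel
#' values are non-negative integers bounded by the bit depth; `white_level`
#' is the intensity taken as full transmission (blank reference) when
#' converting to optical density.
#'
#' @param pixels integer matrix of intensities (rows = image rows).
#' @param bit_depth 8 or 16.
#' @param white_level reference intensity for full transmission; defaults to
#'   the bit-depth maximum `2^bit_depth - 1`.
#' @return An object of class `image_plane`: the pixel matrix with
#'   `bit_depth` and `white_level` attributes.
#' @export
image_plane <- function(pixels, bit_depth = 8L, white_level = NULL) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (length(pixels) == 0L) stop("empty image")
  storage.mode(pixels) <- "integer"
  maxval <- 2L^bit_depth - 1L
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > maxval)
    stop("pixel values must lie in [0, 2^bit_depth - 1]")
  if (is.null(white_level)) white_level <- maxval
  if (white_level <= 0) stop("white_level must be positive")
  structure(pixels, bit_depth = bit_depth, white_level = as.numeric(white_level),
            class = c("image_plane", class(pixels)))
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d, %d-bit, white_level = %g\n",
              nrow(x), ncol(x), attr(x, "bit_depth"), attr(x, "white_level")))
  invisible(x)
}

# ITU-R BT.601 luma weights; Feulgen chromatin absorbs mostly in green, so a
# named single channel is selectable as well.
.reduce_rgb <- function(arr, channel_policy) {
  ch <- match.arg(channel_policy, c("luminance", "red", "green", "blue"))
  if (ch == "luminance") {
    round(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
  } else {
    arr[, , match(ch, c("red", "green", "blue"))]
  }
}

#' Read a grayscale or RGB image as an image plane
#'
#' Reads an 8- or 16-bit TIFF or PNG. RGB inputs are reduced to a single
#' plane: ITU luminance by default, or one named channel (the green channel
#' carries the highest Feulgen contrast).
#'
#' @param path file path, `.tif`/`.tiff` or `.png`.
#' @param channel_policy `"luminance"` (default), `"red"`, `"green"` or
#'   `"blue"`; ignored for grayscale input.
#' @param white_level optional blank-reference intensity; defaults to the
#'   bit-depth maximum.
#' @return An [image_plane].
#' @export
load_image <- function(path, channel_policy = "luminance", white_level = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  if (is_png) {
    raw <- png::readPNG(path, info = TRUE)
    bd <- attr(raw, "info")$bit.depth
  } else {
    raw <- tiff::readTIFF(path, info = TRUE)
    bd <- attr(raw, "bits.per.sample")
  }
  if (is.null(bd) || !bd %in% c(8L, 16L))
    stop("unsupported bit depth: ", if (is.null(bd)) "unknown" else bd)
  maxval <- 2L^as.integer(bd) - 1L
  raw <- raw * maxval  # both readers rescale integer samples to [0, 1]
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] >= 3L) raw <- .reduce_rgb(raw, channel_policy)
    else raw <- raw[, , 1]       # gray + alpha
  }
  image_plane(round(raw), bit_depth = bd, white_level = white_level)
}

#' Write an image plane to TIFF
#'
#' @param image an [image_plane].
#' @param path output path (`.tif`).
#' @return `path`, invisibly. The write/read round trip is pixel-identical.
#' @export
write_image <- function(image, path) {
  bd <- attr(image, "bit_depth")
  maxval <- 2L^bd - 1L
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m / maxval, path, bits.per.sample = bd)
  invisible(path)
}

#' Nucleus region of interest
#'
#' One operator-delineated nucleus, tagged as a lymphocyte internal control
#' or an epithelial (experimental) cell. Geometry is either a closed simple
#' polygon in pixel coordinates or a pre-rasterized pixel set (from a label
#' mask).
#'
#' Coordinates are 0-based; a polygon vertex is `(x = col, y = row)` and the
#' center of pixel `(row r, col c)` is `(c + 0.5, r + 0.5)`. A pixel belongs
#' to the polygon iff its center lies inside under the even-odd rule, so an
#' axis-aligned square of side `s` rasterizes to exactly `s^2` pixels.
#'
#' @param id label, unique within a sample.
#' @param cell_class `"control"` or `"epithelial"`.
#' @param polygon n x 2 matrix of `(x, y)` vertices (closed implicitly), or
#'   `NULL` when `pixels` is given.
#' @param pixels integer matrix with columns `row`, `col` (0-based), or
#'   `NULL` when `polygon` is given.
#' @return An object of class `nucleus_roi`.
#' @export
nucleus_roi <- function(id, cell_class, polygon = NULL, pixels = NULL) {
  cell_class <- match.arg(cell_class, c("control", "epithelial"))
  if (is.null(polygon) == is.null(pixels))
    stop("exactly one of `polygon`, `pixels` must be given")
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L)
      stop("polygon must be an n x 2 matrix, n >= 3")
    if (.polygon_self_intersects(polygon))
      stop("self-intersecting polygon in ROI ", id)
  } else {
    pixels <- as.matrix(pixels)
    colnames(pixels) <- c("row", "col")
  }
  structure(list(id = as.character(id), cell_class = cell_class,
                 polygon = polygon, pixels = pixels),
            class = "nucleus_roi")
}

# Segment intersection test for simple-polygon validation: proper crossings
# between non-adjacent edge pairs, vectorized over all pairs at once.
.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  nxt <- c(2:n, 1L)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- ax[nxt]; by <- ay[nxt]
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  keep <- j > i & j != i + 1L & !(i == 1L & j == n)
  i <- i[keep]; j <- j[keep]
  cross <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
  d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
  d3 <- cross(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
  d4 <- cross(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Rasterize a nucleus ROI onto an image grid
#'
#' Scanline even-odd fill at pixel centers `(col + 0.5, row + 0.5)`,
#' 0-based. Deterministic, and identical whether the ROI arrives as a
#' polygon or as its own rasterized pixel set.
#'
#' @param roi a [nucleus_roi].
#' @param shape integer `(rows, cols)` of the target raster.
#' @return Integer matrix with columns `row`, `col` (0-based), ordered by
#'   row then column.
#' @export
rasterize_roi <- function(roi, shape) {
  if (!is.null(roi$pixels)) {
    px <- roi$pixels
    keep <- px[, 1] >= 0L & px[, 1] < shape[1] & px[, 2] >= 0L & px[, 2] < shape[2]
    px <- px[keep, , drop = FALSE]
    return(px[order(px[, 1], px[, 2]), , drop = FALSE])
  }
  poly <- roi$polygon
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1L), 1]; y2 <- poly[c(2:n, 1L), 2]
  r_lo <- max(0L, floor(min(y1) - 0.5))
  r_hi <- min(shape[1] - 1L, ceiling(max(y1)))
  out_r <- integer(0); out_c <- integer(0)
  if (r_hi >= r_lo) {
    for (r in r_lo:r_hi) {
      y <- r + 0.5
      # half-open edge rule [min(y1,y2), max) avoids double-counting vertices
      hit <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
      if (!any(hit)) next
      xs <- sort(x1[hit] + (y - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        c_lo <- max(0L, ceiling(xs[k] - 0.5))
        c_hi <- min(shape[2] - 1L, ceiling(xs[k + 1L] - 0.5) - 1L)
        if (c_hi >= c_lo) {
          cc <- c_lo:c_hi
          out_r <- c(out_r, rep.int(r, length(cc)))
          out_c <- c(out_c, cc)
        }
      }
    }
  }
  cbind(row = out_r, col = out_c)
}

#' Read nucleus ROIs
#'
#' Two on-disk representations are supported:
#' * a polygon ROI JSON file with schema
#'   `{"rois": [{"id": str, "cell_class": "control"|"epithelial",
#'   "polygon": [[x, y], ...]}, ...]}`;
#' * an integer label-mask TIFF plus a class table CSV with columns
#'   `label, cell_class` (pass the CSV as `class_table`).
#'
#' @param path ROI JSON path, or label-mask TIFF path.
#' @param class_table CSV path mapping mask labels to cell classes; required
#'   for mask input, ignored for JSON.
#' @return List of [nucleus_roi]; every ROI carries a `cell_class`, ids are
#'   unique, polygon geometry validated.
#' @export
load_rois <- function(path, class_table = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(doc$rois)) stop("ROI JSON lacks a 'rois' array")
    rois <- lapply(doc$rois, function(r) {
      if (is.null(r$cell_class)) stop("ROI ", r$id, " missing cell_class")
      poly <- do.call(rbind, lapply(r$polygon, function(v) as.numeric(unlist(v))))
      nucleus_roi(r$id, r$cell_class, polygon = poly)
    })
  } else {
    if (is.null(class_table)) stop("label-mask input requires `class_table`")
    mask <- tiff::readTIFF(path, as.is = TRUE)
    cls <- utils::read.csv(class_table, stringsAsFactors = FALSE)
    if (!all(c("label", "cell_class") %in% names(cls)))
      stop("class table needs columns label, cell_class")
    labs <- sort(unique(mask[mask > 0]))
    rois <- lapply(labs, function(l) {
      idx <- which(mask == l, arr.ind = TRUE)
      cc <- cls$cell_class[match(l, cls$label)]
      if (is.na(cc)) stop("label ", l, " missing from class table")
      nucleus_roi(as.character(l), cc,
                  pixels = cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L))
    })
  }
  ids <- vapply(rois, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate ROI ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rois
}

#' Write nucleus ROIs to the polygon JSON format
#'
#' @param rois list of [nucleus_roi] with polygon geometry.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  doc <- list(rois = lapply(rois, function(r) {
    if (is.null(r$polygon)) stop("ROI ", r$id, " has no polygon geometry")
    list(id = r$id, cell_class = r$cell_class,
         polygon = lapply(seq_len(nrow(r$polygon)),
                          function(i) as.numeric(r$polygon[i, ])))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Check that ROIs are nonoverlapping
#'
#' The measurement protocol requires nonoverlapping nuclei. Reports every
#' pixel claimed by two or more ROIs.
#'
#' @param rois list of [nucleus_roi].
#' @param shape `(rows, cols)` raster shape the ROIs live on.
#' @return List with `ok` (logical), `n_shared_pixels`, and `pairs`, a
#'   data.frame of ROI id pairs that share at least one pixel.
#' @export
check_nonoverlap <- function(rois, shape) {
  owner <- vector("list", length(rois))
  counts <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(rois)) {
    px <- rasterize_roi(rois[[i]], shape)
    idx <- px[, 1] + 1L + px[, 2] * shape[1]
    owner[[i]] <- idx
    counts[idx] <- counts[idx] + 1L
  }
  shared <- which(counts >= 2L)
  pairs <- NULL
  if (length(shared)) {
    hit <- vapply(owner, function(ix) any(ix %in% shared), logical(1))
    ids <- vapply(rois, `[[`, "", "id")
    comb <- utils::combn(which(hit), 2L)
    keep <- apply(comb, 2L, function(p)
      length(intersect(owner[[p[1]]], owner[[p[2]]])) > 0L)
    if (any(keep)) {
      comb <- comb[, keep, drop = FALSE]
      pairs <- data.frame(roi_a = ids[comb[1, ]], roi_b = ids[comb[2, ]],
                          stringsAsFactors = FALSE)
    }
  }
  list(ok = length(shared) == 0L, n_shared_pixels = length(shared),
       shared_pixels = shared, pairs = pairs)
}

#' Read a study layout
#'
#' CSV with columns `sample_id, condition, image_path, roi_path`. Relative
#' paths are resolved against the CSV's own directory.
#'
#' @param path layout CSV path.
#' @return data.frame with the four columns; sample ids unique, conditions
#'   kept in first-appearance order (as a factor's levels).
#' @export
load_study_layout <- function(path) {
  lay <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "condition", "image_path", "roi_path")
  if (!all(need %in% names(lay)))
    stop("layout CSV needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(lay$sample_id)) stop("duplicate sample ids in layout")
  if (nrow(lay) == 0L) stop("empty study layout")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lay$image_path <- fix(lay$image_path)
  lay$roi_path <- fix(lay$roi_path)
  lay$condition <- factor(lay$condition, levels = unique(lay$condition))
  lay
}
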