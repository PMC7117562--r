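#' Ploidy classification thresholds
#'
#' The mild-aneuploidy boundary is a DI of 1.1, strict: a sample is called
#' aneuploid only when its peak DI exceeds 1.1. The moderate boundary is not
#' standardized; 1.40 separates the mild (~1.2) from the moderate (~1.5)
#' regime and is configurable.
#'
#' @param mild threshold above which a sample is mildly aneuploid
#'   (default 1.1).
#' @param moderate threshold above which aneuploidy is moderate
#'   (default 1.40); must exceed `mild`.
#' @return list of class `ploidy_thresholds`.
#' @export
ploidy_thresholds <- function(mild = 1.1, moderate = 1.40) {
  if (!(1 < mild && mild < moderate))
    stop("need 1 < mild < moderate")
  structure(list(mild = mild, moderate = moderate),
            class = "ploidy_thresholds")
}

# Center-anchored uniform binning: bin k covers [(k - 1/2) w, (k + 1/2) w),
# half-open, so bin CENTERS sit at integer multiples of the width and a
# value landing exactly on an edge goes to the upper bin. floor(x/w + 1/2)
# implements exactly that assignment.
.bin_index <- function(x, w) as.integer(floor(x / w + 0.5))

#' Modal IOD of the control nuclei
#'
#' The lymphocyte internal controls are diploid; the mode of their IOD
#' distribution defines the 2N reference. The mode is taken as the center of
#' the maximal-count bin of a uniform histogram whose bin centers sit at
#' integer multiples of the bin width; ties break toward the lower bin.
#'
#' @param control_iods positive IODs of the control nuclei.
#' @param bin_width histogram bin width in IOD units; default
#'   `0.05 * median(control_iods)`, which scales with the slide's intensity
#'   calibration so the mode is equivariant under global rescaling.
#' @return The modal IOD (a bin center).
#' @export
modal_iod <- function(control_iods, bin_width = NULL) {
  if (length(control_iods) == 0L) stop("empty control set")
  if (length(control_iods) < 30L)
    warning(sprintf("only %d control IODs (protocol expects 30)",
                    length(control_iods)))
  if (diff(range(control_iods)) == 0) return(control_iods[1])
  if (is.null(bin_width)) bin_width <- 0.05 * stats::median(control_iods)
  if (bin_width <= 0) stop("bin_width must be positive")
  k <- .bin_index(control_iods, bin_width)
  tab <- table(k)
  kmax <- as.integer(names(tab)[which.max(tab)])  # which.max: first = lowest
  kmax * bin_width
}

#' DNA indices from epithelial IODs
#'
#' `DI = IOD / modal control IOD`: the modal control is the internal diploid
#' (2N) reference assigned DI 1, so a nucleus whose IOD equals the modal
#' control IOD gets DI exactly 1 and a 4N nucleus gets DI 2. DI is invariant
#' under any global rescaling of the slide's intensities.
#'
#' @param epithelial_iods positive IODs.
#' @param modal_control_iod positive reference IOD from [modal_iod()].
#' @return Numeric vector of DNA indices.
#' @export
compute_di <- function(epithelial_iods, modal_control_iod) {
  if (!is.numeric(modal_control_iod) || modal_control_iod <= 0)
    stop("modal_control_iod must be positive")
  epithelial_iods / modal_control_iod
}

#' Build a DI histogram
#'
#' Uniform bins with centers at integer multiples of `bin_width`, half-open
#' `[center - w/2, center + w/2)` so each DI falls in exactly one bin and a
#' value on an interior edge goes to the upper bin. The range runs from 0 to
#' at least `max(3, max DI)`, covering 2N through 4N-and-beyond.
#'
#' @param di_values positive DNA indices.
#' @param bin_width bin width in DI units (default 0.05, resolving 2N from
#'   4N while keeping several cells per bin at n around 150-200).
#' @param range_max upper limit of binned range; default
#'   `max(3, max(di_values))`.
#' @return Object of class `di_histogram`: list with `bin_centers`,
#'   `bin_edges`, `counts`, `bin_width`. `sum(counts)` equals
#'   `length(di_values)`.
#' @export
build_histogram <- function(di_values, bin_width = 0.05, range_max = NULL) {
  if (length(di_values) == 0L) stop("no DI values")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (is.null(range_max)) range_max <- max(3, max(di_values))
  kmax <- max(.bin_index(range_max, bin_width), .bin_index(di_values, bin_width))
  centers <- (0:kmax) * bin_width
  k <- .bin_index(di_values, bin_width)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  structure(list(bin_centers = centers,
                 bin_edges = c(centers - bin_width / 2, centers[kmax + 1L] + bin_width / 2),
                 counts = counts, bin_width = bin_width),
            class = "di_histogram")
}

#' @export
print.di_histogram <- function(x, ...) {
  occ <- which(x$counts > 0)
  cat(sprintf("<di_histogram> %d cells in %d bins (width %g), occupied DI %g-%g\n",
              sum(x$counts), length(x$counts), x$bin_width,
              x$bin_centers[min(occ)], x$bin_centers[max(occ)]))
  invisible(x)
}

#' Plot a DI histogram
#'
#' DI versus number of cells, with the diploid reference (DI 1) and the
#' mild-aneuploidy threshold marked.
#'
#' @param x a `di_histogram`.
#' @param thresholds a [ploidy_thresholds] for the threshold line.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.di_histogram <- function(x, thresholds = ploidy_thresholds(), ...) {
  keep <- x$bin_centers <= max(x$bin_centers[x$counts > 0]) + 5 * x$bin_width
  bp <- graphics::barplot(x$counts[keep], names.arg = x$bin_centers[keep],
                          xlab = "DNA index", ylab = "Number of cells",
                          border = NA, space = 0, ...)
  sc <- function(v) stats::approx(x$bin_centers[keep], bp[, 1], xout = v)$y
  graphics::abline(v = sc(1), lty = 2)
  graphics::abline(v = sc(thresholds$mild), lty = 3)
  invisible(bp)
}

#' Peak DI of a histogram
#'
#' The DI at the maximum of the sample's DI histogram, taken as the
#' representative ploidy value of the sample. Ties break toward the lower
#' bin (conservative toward diploid).
#'
#' @param histogram a `di_histogram`.
#' @return The center of the maximal-count bin.
#' @export
peak_di <- function(histogram) {
  if (all(histogram$counts == 0L)) stop("all-zero histogram")
  histogram$bin_centers[which.max(histogram$counts)]
}

#' Classify sample ploidy from its peak DI
#'
#' Diploid when `peak_di <= mild` (the 1.1 boundary is strict: 1.10 itself
#' is still diploid), mild aneuploidy on `(mild, moderate]`, moderate
#' aneuploidy above. The aneuploid flag is true for any non-diploid call.
#'
#' @param peak_di positive peak DI.
#' @param thresholds a [ploidy_thresholds].
#' @return `"diploid"`, `"mild"` or `"moderate"`.
#' @export
classify_ploidy <- function(peak_di, thresholds = ploidy_thresholds()) {
  if (peak_di <= 0) stop("peak_di must be positive")
  if (peak_di <= thresholds$mild) "diploid"
  else if (peak_di <= thresholds$moderate) "mild"
  else "moderate"
}

#' Analyze one sample's measurements into a ploidy result
#'
#' Composes the per-sample pipeline: modal control IOD, epithelial DIs, DI
#' histogram, peak DI, ploidy class. Deterministic given inputs and
#' configuration.
#'
#' @param measurements data.frame from [measure_sample()] (columns
#'   `roi_id, cell_class, iod`, ...).
#' @param sample_id,condition identifiers carried into the result.
#' @param bin_width DI histogram bin width (default 0.05).
#' @param control_bin_width IOD bin width for the modal estimate; default
#'   `0.05 * median control IOD` (see [modal_iod()]).
#' @param thresholds a [ploidy_thresholds].
#' @return Object of class `sample_result`: list with `sample_id`,
#'   `condition`, `n_control`, `n_epithelial`, `modal_control_iod`,
#'   `di_values`, `histogram`, `peak_di`, `ploidy_class`, `aneuploid`.
#' @export
analyze_sample <- function(measurements, sample_id = "sample",
                           condition = NA_character_, bin_width = 0.05,
                           control_bin_width = NULL,
                           thresholds = ploidy_thresholds()) {
  ctrl <- measurements$iod[measurements$cell_class == "control"]
  epi <- measurements$iod[measurements$cell_class == "epithelial"]
  if (length(ctrl) == 0L) stop("no control measurements in sample ", sample_id)
  if (length(epi) == 0L) stop("no epithelial measurements in sample ", sample_id)
  modal <- modal_iod(ctrl, bin_width = control_bin_width)
  di <- compute_di(epi, modal)
  hist <- build_histogram(di, bin_width = bin_width)
  pk <- peak_di(hist)
  cls <- classify_ploidy(pk, thresholds)
  structure(list(sample_id = sample_id, condition = condition,
                 n_control = length(ctrl), n_epithelial = length(epi),
                 modal_control_iod = modal, di_values = di, histogram = hist,
                 peak_di = pk, ploidy_class = cls,
                 aneuploid = cls != "diploid"),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf(
    "<sample_result> %s (%s): %d controls, %d epithelial; modal IOD %.4g; peak DI %.3g [%s]\n",
    x$sample_id, x$condition, x$n_control, x$n_epithelial,
    x$modal_control_iod, x$peak_di, x$ploidy_class))
  invisible(x)
}

#' Serialize a sample result to JSON
#'
#' @param result a `sample_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_result <- function(result, path) {
  out <- result[c("sample_id", "condition", "n_control", "n_epithelial",
                  "modal_control_iod", "peak_di", "ploidy_class", "aneuploid")]
  out$condition <- as.character(out$condition)
  out$di_values <- result$di_values
  out$histogram <- list(bin_centers = result$histogram$bin_centers,
                        counts = result$histogram$counts,
                        bin_width = result$histogram$bin_width)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
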