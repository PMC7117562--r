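#' Pipeline run configuration
#'
#' All tunables of the measurement-to-statistics pipeline with their
#' defaults, serialized alongside every output for provenance.
#'
#' @param channel_policy RGB reduction for [load_image()].
#' @param white_level blank reference policy for [to_optical_density()]:
#'   `NULL` (bit-depth maximum), `"background"`, or a number.
#' @param epsilon OD clamp fraction.
#' @param min_area minimum nucleus area in pixels.
#' @param overlap `"error"` or `"warn"` on overlapping ROIs.
#' @param bin_width DI histogram bin width.
#' @param control_bin_width modal-IOD bin width (`NULL`: 5% of the median
#'   control IOD).
#' @param mild_threshold,moderate_threshold ploidy cutoffs
#'   (see [ploidy_thresholds()]).
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @param alpha significance level.
#' @param condition_order progression order for the comparison matrix
#'   (`NULL`: layout order).
#' @param seed seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @return list of class `aic_config`.
#' @export
aic_config <- function(channel_policy = "luminance", white_level = NULL,
                       epsilon = 1e-4, min_area = 10L,
                       overlap = "error", bin_width = 0.05,
                       control_bin_width = NULL, mild_threshold = 1.1,
                       moderate_threshold = 1.40, variant = "pooled",
                       alpha = 0.05, condition_order = NULL, seed = 1L) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!(1 < mild_threshold && mild_threshold < moderate_threshold))
    stop("need 1 < mild_threshold < moderate_threshold")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(channel_policy = channel_policy, white_level = white_level,
                 epsilon = epsilon, min_area = as.integer(min_area),
                 overlap = overlap, bin_width = bin_width,
                 control_bin_width = control_bin_width,
                 mild_threshold = mild_threshold,
                 moderate_threshold = moderate_threshold,
                 variant = variant, alpha = alpha,
                 condition_order = condition_order, seed = as.integer(seed)),
            class = "aic_config")
}

# CSVs carry the md5 of the serialized config as a leading comment so any
# output can be traced to the exact configuration that produced it.
.write_csv_tagged <- function(df, path, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_md5 ", config_hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
}

#' Run the full study pipeline
#'
#' For every sample in the layout: load image and ROIs, measure per-nucleus
#' IOD, normalize to the modal control IOD, build the DI histogram, extract
#' peak DI and ploidy class. Then summarize each condition group and
#' compute the pairwise one-tailed t-test matrix over per-sample peak DIs.
#' Deterministic given inputs and config: a rerun reproduces every output
#' byte for byte.
#'
#' Outputs written under `out_dir`: `samples/<id>.json` per-sample results,
#' `group_summary.csv` (condition, n, mean/SD/range of peak DI, aneuploid
#' fraction), `comparison_pairs.csv` and `p_matrix.csv` (pairwise tests),
#' `config.json`, and `warnings.log`.
#'
#' @param layout a layout data.frame ([load_study_layout()]) or the path to
#'   a layout CSV.
#' @param config an [aic_config()].
#' @param out_dir output directory.
#' @return list with `samples` (list of `sample_result`), `groups`
#'   (group summary data.frame), `comparisons` (pairwise test data.frame),
#'   `p_matrix` (character matrix), `warnings` (character vector).
#' @export
run_pipeline <- function(layout, config = aic_config(), out_dir = NULL) {
  if (is.character(layout)) layout <- load_study_layout(layout)
  if (nrow(layout) == 0L) stop("empty study layout")
  thr <- ploidy_thresholds(config$mild_threshold, config$moderate_threshold)
  warns <- character(0)
  samples <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    sid <- layout$sample_id[i]
    res <- withCallingHandlers(
      {
        img <- load_image(layout$image_path[i],
                          channel_policy = config$channel_policy)
        rois <- load_rois(layout$roi_path[i])
        meas <- measure_sample(img, rois, white_level = config$white_level,
                               epsilon = config$epsilon,
                               min_area = config$min_area,
                               overlap = config$overlap)
        analyze_sample(meas, sample_id = sid,
                       condition = as.character(layout$condition[i]),
                       bin_width = config$bin_width,
                       control_bin_width = config$control_bin_width,
                       thresholds = thr)
      },
      warning = function(w) {
        warns <<- c(warns, paste0(sid, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      },
      error = function(e) stop("sample ", sid, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    samples[[i]] <- res
    message("analyzed ", sid, ": peak DI ", format(res$peak_di),
            " [", res$ploidy_class, "]")
  }

  conds <- if (is.null(config$condition_order))
    levels(factor(layout$condition, levels = unique(layout$condition)))
  else config$condition_order
  peaks <- vapply(samples, `[[`, numeric(1), "peak_di")
  samp_cond <- vapply(samples, function(s) as.character(s$condition), "")
  groups <- do.call(rbind, lapply(conds, function(cc)
    summarize_group(peaks[samp_cond == cc], condition = cc, thresholds = thr)))
  comparisons <- if (length(conds) >= 2L)
    comparison_matrix(groups, order = conds, variant = config$variant,
                      alpha = config$alpha)
  else NULL
  pmat <- if (!is.null(comparisons)) format_p_matrix(comparisons) else NULL

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "samples"), showWarnings = FALSE,
               recursive = TRUE)
    cfg_path <- file.path(out_dir, "config.json")
    cfg <- config
    cfg$white_level <- if (is.null(cfg$white_level)) "max" else cfg$white_level
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    hash <- unname(tools::md5sum(cfg_path))
    for (s in samples)
      write_sample_result(s, file.path(out_dir, "samples",
                                       paste0(s$sample_id, ".json")))
    .write_csv_tagged(groups, file.path(out_dir, "group_summary.csv"), hash)
    if (!is.null(comparisons)) {
      .write_csv_tagged(comparisons,
                        file.path(out_dir, "comparison_pairs.csv"), hash)
      pm <- data.frame(condition = rownames(pmat), pmat, check.names = FALSE,
                       stringsAsFactors = FALSE)
      .write_csv_tagged(pm, file.path(out_dir, "p_matrix.csv"), hash)
    }
    writeLines(warns, file.path(out_dir, "warnings.log"))
  }
  list(samples = samples, groups = groups, comparisons = comparisons,
       p_matrix = pmat, warnings = warns)
}
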