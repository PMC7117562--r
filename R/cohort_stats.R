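#' Summarize a condition group's per-sample peak DIs
#'
#' Mean, sample SD (n - 1), range and aneuploid fraction over the group's
#' per-sample peak DNA indices — the row structure of a group summary
#' table: "mean DI (range; SD)" plus "fraction of samples with aneuploidy".
#'
#' @param peak_dis per-sample peak DIs, or a list of `sample_result`s.
#' @param condition group label.
#' @param thresholds a [ploidy_thresholds] for the aneuploidy call
#'   (`peak DI > mild`).
#' @return One-row data.frame of class `group_summary`: `condition, n,
#'   mean_di, sd_di, min_di, max_di, aneuploid_count, aneuploid_fraction`.
#' @export
summarize_group <- function(peak_dis, condition = NA_character_,
                            thresholds = ploidy_thresholds()) {
  if (is.list(peak_dis) && length(peak_dis) &&
      inherits(peak_dis[[1]], "sample_result")) {
    if (is.na(condition)) condition <- as.character(peak_dis[[1]]$condition)
    peak_dis <- vapply(peak_dis, `[[`, numeric(1), "peak_di")
  }
  n <- length(peak_dis)
  if (n == 0L) stop("empty group")
  ane <- sum(peak_dis > thresholds$mild)
  out <- data.frame(condition = condition, n = n,
                    mean_di = mean(peak_dis),
                    sd_di = if (n >= 2L) stats::sd(peak_dis) else NA_real_,
                    min_di = min(peak_dis), max_di = max(peak_dis),
                    aneuploid_count = ane, aneuploid_fraction = ane / n,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_summary", class(out))
  out
}

#' One-tailed unpaired t-test from group summaries
#'
#' The classical two-sample test computed from `(mean, SD, n)` per group.
#' The pooled variant assumes equal variances:
#' `sp^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a+n_b-2)`,
#' `t = (mean_b - mean_a) / (sp * sqrt(1/n_a + 1/n_b))`, `df = n_a+n_b-2`.
#' The Welch variant uses per-group variances with Satterthwaite df. The
#' one-tailed p is the tail probability of `t` under the stated alternative.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (`n >= 2`,
#'   SDs non-negative and not both zero).
#' @param variant `"pooled"` (default; the classical unpaired test) or
#'   `"welch"`.
#' @param alternative `"greater"` (default; b exceeds a), `"less"`, or
#'   `"two.sided"`.
#' @param alpha significance level (default 0.05).
#' @param group_a,group_b optional labels.
#' @return One-row data.frame of class `ttest_result`:
#'   `group_a, group_b, variant, alternative, t, df, p, significant`.
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                variant = c("pooled", "welch"),
                                alternative = c("greater", "less", "two.sided"),
                                alpha = 0.05,
                                group_a = "a", group_b = "b") {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  if (n_a < 2L || n_b < 2L) stop("each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0) stop("negative SD")
  if (sd_a == 0 && sd_b == 0 && mean_a == mean_b)
    stop("degenerate: zero variance in both groups with equal means")
  if (variant == "pooled") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_b - mean_a) / se
  p <- switch(alternative,
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df, lower.tail = TRUE),
              two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  out <- data.frame(group_a = group_a, group_b = group_b, variant = variant,
                    alternative = alternative, t = t, df = df, p = p,
                    significant = p < alpha, stringsAsFactors = FALSE)
  class(out) <- c("ttest_result", class(out))
  out
}

#' One-tailed unpaired t-test from raw per-sample DIs
#'
#' Identical to [t_test_from_summary()] applied to the two lists' means,
#' SDs and sizes.
#'
#' @param di_a,di_b numeric vectors of per-sample peak DIs, length >= 2.
#' @inheritParams t_test_from_summary
#' @return A `ttest_result` (see [t_test_from_summary()]).
#' @export
t_test_from_samples <- function(di_a, di_b, variant = c("pooled", "welch"),
                                alternative = c("greater", "less", "two.sided"),
                                alpha = 0.05,
                                group_a = "a", group_b = "b") {
  if (length(di_a) < 2L || length(di_b) < 2L) stop("each list needs length >= 2")
  t_test_from_summary(mean(di_a), stats::sd(di_a), length(di_a),
                      mean(di_b), stats::sd(di_b), length(di_b),
                      variant = variant, alternative = alternative,
                      alpha = alpha, group_a = group_a, group_b = group_b)
}

#' Pairwise one-tailed t-test matrix across condition groups
#'
#' One test per unordered pair of conditions, laid out in the given
#' progression order. By default the alternative for each pair is that the
#' LATER condition in the order has the greater mean DI, matching the
#' framing of neoplastic progression; `alternative` overrides this for
#' every pair.
#'
#' @param summaries data.frame with columns `condition, mean_di, sd_di, n`
#'   (e.g. rbind of [summarize_group()] rows).
#' @param order character vector of condition labels fixing the progression
#'   order; default the row order of `summaries`.
#' @param variant `"pooled"` or `"welch"`.
#' @param alternative `NULL` (default: later-greater per the order) or a
#'   fixed alternative applied to every pair.
#' @param alpha significance level.
#' @return data.frame of `ttest_result` rows, one per pair `(i < j)` in
#'   order, `C(k, 2)` rows for `k` groups.
#' @export
comparison_matrix <- function(summaries, order = NULL,
                              variant = c("pooled", "welch"),
                              alternative = NULL, alpha = 0.05) {
  variant <- match.arg(variant)
  if (is.null(order)) order <- as.character(summaries$condition)
  if (!all(order %in% summaries$condition))
    stop("unknown condition label(s): ",
         paste(setdiff(order, summaries$condition), collapse = ", "))
  s <- summaries[match(order, summaries$condition), , drop = FALSE]
  if (nrow(s) < 2L) stop("need at least 2 groups")
  res <- list()
  for (i in 1:(nrow(s) - 1L)) {
    for (j in (i + 1L):nrow(s)) {
      res[[length(res) + 1L]] <- t_test_from_summary(
        s$mean_di[i], s$sd_di[i], s$n[i],
        s$mean_di[j], s$sd_di[j], s$n[j],
        variant = variant,
        alternative = if (is.null(alternative)) "greater" else alternative,
        alpha = alpha, group_a = order[i], group_b = order[j])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Render a comparison matrix as an upper-triangular p-value table
#'
#' Square character matrix in condition order with p values rounded to two
#' decimals in the upper triangle and `"X"` elsewhere, mirroring how such
#' pairwise tables are printed.
#'
#' @param matrix_df output of [comparison_matrix()].
#' @param digits rounding for display (default 2).
#' @return Character matrix with condition dimnames.
#' @export
format_p_matrix <- function(matrix_df, digits = 2L) {
  conds <- unique(c(matrix_df$group_a, matrix_df$group_b))
  m <- matrix("X", length(conds), length(conds), dimnames = list(conds, conds))
  for (r in seq_len(nrow(matrix_df))) {
    m[matrix_df$group_a[r], matrix_df$group_b[r]] <-
      formatC(round(matrix_df$p[r], digits), format = "f", digits = digits)
  }
  m
}
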