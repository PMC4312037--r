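# Cross-modality and cross-group statistics: per-subject infarct table,
# Pearson R^2 with manual outlier exclusion, paired and two-sample tests,
# agreement report assembly.

#' Published per-subject infarct percentages
#'
#' The eight CT-derived / histology-derived percent-infarct pairs of the
#' animal study the pipeline emulates, shipped as a packaged CSV. Subject
#' 5 is flagged: its CT image was degraded by motion streaks near the
#' ribs, which the segmentation misread as enhancement.
#'
#' Note the published table's AVERAGE/ST.DEV. summary row is internally
#' inconsistent with its own columns (the column means are 32.2 for CT
#' and 30.5 for histology, the reverse of the printed summary); the
#' correlation statistics are unaffected.
#'
#' @return data.frame with columns \code{subject_id},
#'   \code{ct_infarct_pct}, \code{hist_infarct_pct},
#'   \code{difference_pct} (CT minus histology), \code{motion_artifact}.
#' @export
table1_records <- function() {
  path <- system.file("extdata", "table1_infarct_pct.csv",
                      package = "cardiomict", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$difference_pct <- df$ct_infarct_pct - df$hist_infarct_pct
  df[, c("subject_id", "ct_infarct_pct", "hist_infarct_pct",
         "difference_pct", "motion_artifact")]
}

#' Mean and standard deviation
#'
#' @param values numeric vector, length >= 2.
#' @param ddof degrees-of-freedom correction: 1 (sample SD, default) or 0
#'   (population SD).
#' @return named numeric \code{c(mean, sd)}.
#' @export
mean_sd <- function(values, ddof = 1L) {
  if (length(values) < 2L) stop("need at least 2 values for an SD")
  if (!ddof %in% c(0L, 1L)) stop("'ddof' must be 0 or 1")
  n <- length(values)
  s <- stats::sd(values)                     # divisor n - 1
  if (ddof == 0L) s <- s * sqrt((n - 1) / n)
  c(mean = mean(values), sd = s)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 2, each with non-zero
#'   variance.
#' @return R^2 in [0, 1].
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)^2
}

#' Paired two-sided t-test
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list \code{(statistic, p)}. Identical vectors give
#'   \code{statistic = 0, p = 1}; a constant non-zero difference is a
#'   degenerate test and errors.
#' @export
paired_test <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(statistic = 0, p = 1))
    stop("degenerate paired test: constant non-zero differences")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Two-sample Welch t-test
#'
#' @param a,b numeric vectors, each length >= 2.
#' @return list \code{(statistic, p)}. Two identical constant groups give
#'   \code{statistic = 0, p = 1}; constant groups with different means are
#'   degenerate and error.
#' @export
group_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p = 1))
    stop("degenerate group test: both groups constant")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Cross-modality agreement report
#'
#' Assembles per-modality means/SDs, the all-subject R^2, the R^2 after
#' dropping the listed subjects (manual exclusion, mirroring the removal
#' of a motion-corrupted subject rather than automated outlier
#' detection), the paired t-test p-value, and per-subject differences.
#'
#' @param records data.frame with columns \code{subject_id},
#'   \code{ct_infarct_pct}, \code{hist_infarct_pct}.
#' @param exclude_ids subject ids to drop from the excluded-R^2 (and only
#'   that statistic); default none.
#' @return object of class \code{agreement_report}.
#' @export
agreement_report <- function(records, exclude_ids = integer(0)) {
  need <- c("subject_id", "ct_infarct_pct", "hist_infarct_pct")
  if (!all(need %in% names(records)))
    stop("records must have columns subject_id, ct_infarct_pct, hist_infarct_pct")
  ok <- stats::complete.cases(records[, need])
  records <- records[ok, ]
  if (nrow(records) < 2L) stop("need at least 2 usable records")
  ct <- records$ct_infarct_pct
  hi <- records$hist_infarct_pct
  keep <- !(records$subject_id %in% exclude_ids)
  if (sum(keep) < 2L) stop("exclusion leaves fewer than 2 records")
  pt <- paired_test(ct, hi)
  structure(
    list(n = nrow(records),
         mean_ct = mean(ct), sd_ct = stats::sd(ct),
         mean_hist = mean(hi), sd_hist = stats::sd(hi),
         r2_all = pearson_r2(ct, hi),
         r2_excluded = pearson_r2(ct[keep], hi[keep]),
         excluded_ids = records$subject_id[!keep],
         paired_p = pt$p,
         differences = stats::setNames(ct - hi, records$subject_id)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, digits = 4, ...) {
  cat("Cross-modality infarct agreement\n")
  cat(sprintf("  n = %d subjects\n", x$n))
  cat(sprintf("  CT:        %.1f +/- %.1f %%\n", x$mean_ct, x$sd_ct))
  cat(sprintf("  histology: %.1f +/- %.1f %%\n", x$mean_hist, x$sd_hist))
  cat(sprintf("  R^2 (all) = %.*f", digits, x$r2_all))
  if (length(x$excluded_ids))
    cat(sprintf(" | R^2 (excl. %s) = %.*f",
                paste(x$excluded_ids, collapse = ","), digits,
                x$r2_excluded))
  cat(sprintf("\n  paired t-test p = %.3f\n", x$paired_p))
  invisible(x)
}
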