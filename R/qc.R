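# Quality control: quantify how similar two batches' deconvoluted SDA
# value distributions are, via paired-quantile (Q-Q) tables, RMSE against
# the 45-degree identity line, and the two-sample Kolmogorov-Smirnov
# statistic.  QC is computed on hold-out pixel samples, never on the
# training sample used for vector extraction or fit estimation.

#' Paired-quantile (Q-Q) table
#'
#' Computes matched quantiles of two samples at probabilities
#' `(i - 0.5) / n` for `i = 1..n_quantiles`, linearly interpolating order
#' statistics.  Equal distributions put all pairs on the identity line.
#'
#' @param source,target numeric samples (at least 2 values each;
#'   `n_quantiles` or more recommended).
#' @param n_quantiles number of quantiles (default 1000).
#' @param channel optional label (`"hem"` or `"dab"`).
#' @return object of class `qq_table`: list with `n_quantiles`, `probs`,
#'   `q_source`, `q_target`, `channel`.
#' @export
qq_table <- function(source, target, n_quantiles = 1000L, channel = NA_character_) {
  if (length(source) < 2L || length(target) < 2L)
    stop("need at least 2 values per sample")
  structure(list(n_quantiles = as.integer(n_quantiles),
                 probs = mid_probs(n_quantiles),
                 q_source = sample_quantiles(source, n_quantiles),
                 q_target = sample_quantiles(target, n_quantiles),
                 channel = channel),
            class = "qq_table")
}

#' Q-Q root-mean-square error
#'
#' RMSE of the paired quantiles against the identity line:
#' `sqrt(mean((q_source - q_target)^2))`.  Zero iff the quantile vectors
#' coincide.  As a rule of thumb, an RMSE above 0.05 after colour matching
#' signals residual intensity deformation worth correcting by a
#' distribution-fitting step.
#'
#' @param table a [qq_table()].
#' @return nonnegative scalar.
#' @export
qq_rmse <- function(table) {
  stopifnot(inherits(table, "qq_table"))
  sqrt(mean((table$q_source - table$q_target)^2))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The exact supremum of the absolute difference between the two empirical
#' cumulative distribution functions, evaluated over the pooled sample.
#'
#' @param source,target non-empty numeric samples.
#' @return KS statistic in `[0, 1]`.
#' @export
ks_statistic <- function(source, target) {
  stopifnot(length(source) > 0, length(target) > 0)
  pooled <- sort(unique(c(source, target)))
  f_s <- findInterval(pooled, sort(source)) / length(source)
  f_t <- findInterval(pooled, sort(target)) / length(target)
  max(abs(f_s - f_t))
}

#' @rdname ks_statistic
#' @return for `ks_test`, a list with `statistic` and `p.value` (asymptotic
#'   two-sample p-value).
#' @export
ks_test <- function(source, target) {
  stat <- ks_statistic(source, target)
  pv <- suppressWarnings(
    stats::ks.test(source, target, exact = FALSE)$p.value)
  list(statistic = stat, p.value = pv)
}

#' Distribution-similarity report for one channel and batch pair
#'
#' Bundles the Q-Q RMSE and the KS statistic/p-value comparing a batch's
#' deconvoluted channel values with the target's, at one pipeline stage
#' (`before_matching`, `after_matching` or `after_fitting`).
#'
#' @param source,target numeric hold-out samples of deconvoluted values.
#' @param n_quantiles Q-Q resolution.
#' @param stage pipeline stage label.
#' @param channel channel label (`"hem"` or `"dab"`).
#' @return object of class `qc_report`.
#' @export
qc_report <- function(source, target, n_quantiles = 1000L,
                      stage = c("before_matching", "after_matching",
                                "after_fitting"),
                      channel = NA_character_) {
  stage <- match.arg(stage)
  tab <- qq_table(source, target, n_quantiles, channel)
  kt <- ks_test(source, target)
  structure(list(rmse = qq_rmse(tab),
                 ks_stat = kt$statistic,
                 ks_pvalue = kt$p.value,
                 n_source = length(source), n_target = length(target),
                 stage = stage, channel = channel, qq = tab),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s / %s: RMSE = %.4f, KS = %.4f (p = %.3g)\n",
              x$stage, x$channel, x$rmse, x$ks_stat, x$ks_pvalue))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(stage = x$stage, channel = x$channel, rmse = x$rmse,
             ks_stat = x$ks_stat, ks_pvalue = x$ks_pvalue,
             n_source = x$n_source, n_target = x$n_target,
             stringsAsFactors = FALSE)
}
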