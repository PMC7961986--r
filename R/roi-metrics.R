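#' ROI histogram statistics and group summaries
#'
#' Descriptive statistics of per-voxel metric values within a region of
#' interest (mean, SD, skewness, kurtosis) and cohort-level group summaries.
#' Kurtosis uses the non-excess moment-ratio convention (a normal
#' distribution has kurtosis 3); skewness and kurtosis use population central
#' moments, the SD uses the n-1 denominator. Statistics are always computed
#' from raw voxel values, never from binned histograms.
#'
#' @name roi_metrics
NULL

#' Histogram statistics of one ROI sample
#'
#' @param values finite per-voxel metric values, non-empty.
#' @return list with `n`, `mean`, `sd`, `skewness`, `kurtosis`; skewness and
#'   kurtosis are `NA` for a constant sample (sd = 0).
#' @export
histogram_stats <- function(values) {
  values <- as.numeric(values)
  assert_that(length(values) >= 1, "empty ROI sample")
  assert_that(all(is.finite(values)), "ROI values must be finite")
  n <- length(values)
  mu <- mean(values)
  sdv <- stats::sd(values)
  if (n < 2 || sdv == 0) {
    return(list(n = n, mean = mu, sd = if (n < 2) NA_real_ else 0,
                skewness = NA_real_, kurtosis = NA_real_))
  }
  d <- values - mu
  m2 <- mean(d^2)
  list(n = n, mean = mu, sd = sdv,
       skewness = mean(d^3) / m2^1.5,
       kurtosis = mean(d^4) / m2^2)
}

#' Relative difference between group means, in percent
#'
#' `100 * |mean_without - mean_with| / mean_with`, rounded to the nearest
#' integer percent; the with-event group mean is the reference denominator.
#'
#' @param mean_with reference group mean (nonzero).
#' @param mean_without comparison group mean.
#' @return integer percent.
#' @export
relative_group_difference <- function(mean_with, mean_without) {
  assert_that(is_number(mean_with) && mean_with != 0,
              "reference mean must be nonzero")
  assert_that(is_number(mean_without), "comparison mean must be a number")
  round(100 * abs(mean_without - mean_with) / abs(mean_with))
}

#' Per-group summary of subject-level ROI means
#'
#' @param subject_means data.frame with columns `subject_id`, `metric`,
#'   `group`, `mean` (one row per subject and metric).
#' @param groups allowed group labels.
#' @return data.frame: `metric`, `group`, `n`, `mean`, `sd` (SD of
#'   subject-level means; 0 for a single subject).
#' @export
cohort_summary <- function(subject_means,
                           groups = c("with_LRF", "without_LRF")) {
  need <- c("subject_id", "metric", "group", "mean")
  assert_that(all(need %in% names(subject_means)),
              "subject_means must have columns %s",
              paste(need, collapse = ", "))
  bad <- setdiff(unique(subject_means$group), groups)
  assert_that(length(bad) == 0, "unknown group label(s): %s",
              paste(bad, collapse = ", "))
  out <- do.call(rbind, lapply(split(
    subject_means, subject_means[c("metric", "group")], drop = TRUE),
    function(d) data.frame(metric = d$metric[1], group = d$group[1],
                           n = nrow(d), mean = mean(d$mean),
                           sd = if (nrow(d) > 1) stats::sd(d$mean) else 0)))
  rownames(out) <- NULL
  out[order(out$metric, out$group), ]
}
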