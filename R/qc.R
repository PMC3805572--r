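#' Detection filter
#'
#' Keeps features detected -- non-missing and strictly positive -- in at
#' least `min_fraction` of all runs. The strict default of 1.0 mirrors the
#' common practice of retaining only features present in every injection
#' before metabolome-wide testing.
#'
#' @param table a `feature_table`.
#' @param min_fraction required detected fraction of runs in `[0, 1]`.
#' @return the filtered `feature_table` (feature order preserved).
#' @export
detection_filter <- function(table, min_fraction = 1.0) {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must lie in [0, 1]")
  if (ncol(table$intensities) < 1) stop("table has no runs")
  detected <- !is.na(table$intensities) & table$intensities > 0
  frac <- rowMeans(detected)
  table[frac >= min_fraction, ]
}

per_sample_cv <- function(table, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  samples <- unique(table$runs$sample_id)
  out <- matrix(NA_real_, nrow(table$intensities), length(samples),
                dimnames = list(table$features$feature_id, samples))
  for (j in seq_along(samples)) {
    cols <- table$runs$sample_id == samples[j]
    x <- table$intensities[, cols, drop = FALSE]
    n_ok <- rowSums(!is.na(x))
    m <- rowMeans(x, na.rm = TRUE)
    ss <- rowSums((x - m)^2, na.rm = TRUE)
    denom <- if (sd_convention == "sample") n_ok - 1 else n_ok
    s <- sqrt(ss / denom)
    cv <- ifelse(n_ok >= 2,
                 ifelse(m > 0, 100 * s / m, ifelse(ss == 0, 0, Inf)),
                 NA_real_)
    out[, j] <- cv
  }
  out
}

#' Per-feature technical-replicate percent CV
#'
#' Within each sample, the CV of a feature is `100 * sd / mean` over that
#' sample's replicate intensities (missing replicates excluded; samples
#' with fewer than two usable replicates are skipped). The per-feature
#' summary is the median (default) or mean of those per-sample CVs. The SD
#' uses the `n - 1` sample convention by default -- replicate triplicates
#' are a sample -- with the population (`n`) convention selectable.
#'
#' @param table a `feature_table`.
#' @param aggregate `"median"` (default) or `"mean"` across samples.
#' @param sd_convention `"sample"` (n-1, default) or `"population"` (n).
#' @return named numeric vector of percent CVs (NA when no sample has two
#'   usable replicates).
#' @export
replicate_cv <- function(table, aggregate = c("median", "mean"),
                         sd_convention = c("sample", "population")) {
  aggregate <- match.arg(aggregate)
  cvs <- per_sample_cv(table, sd_convention)
  f <- if (aggregate == "median") stats::median else mean
  out <- apply(cvs, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else f(v)
  })
  stats::setNames(out, table$features$feature_id)
}

#' Replicate-precision filter
#'
#' Keeps features whose aggregated replicate percent CV is at most
#' `max_cv_pct` (default 10, the conventional high-quality cut for
#' triplicate LC-MS injections).
#'
#' @inheritParams replicate_cv
#' @param max_cv_pct CV threshold in percent.
#' @return list with `table` (filtered) and `report` (a `qc_report`).
#' @export
cv_filter <- function(table, max_cv_pct = 10,
                      aggregate = c("median", "mean"),
                      sd_convention = c("sample", "population")) {
  cv <- replicate_cv(table, aggregate, sd_convention)
  keep <- !is.na(cv) & cv <= max_cv_pct
  detected <- !is.na(table$intensities) & table$intensities > 0
  report <- structure(list(
    n_input_features = nrow(table$intensities),
    n_detected_all = sum(rowMeans(detected) >= 1),
    per_feature_cv = cv,
    n_pass_cv = sum(keep),
    parameters = list(max_cv_pct = max_cv_pct,
                      aggregate = match.arg(aggregate),
                      sd_convention = match.arg(sd_convention))),
    class = "qc_report")
  list(table = table[keep, ], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "qc_report: %d features in; %d detected in all runs; ",
    "%d pass CV <= %g%% (%s of per-sample CVs, %s SD)\n"),
    x$n_input_features, x$n_detected_all, x$n_pass_cv,
    x$parameters$max_cv_pct, x$parameters$aggregate,
    x$parameters$sd_convention))
  invisible(x)
}

#' Collapse technical replicates by averaging
#'
#' One column per sample, the mean of its non-missing replicate
#' intensities; a sample whose replicates are all missing for a feature
#' yields a missing cell.
#'
#' @param table a `feature_table`.
#' @return a `feature_table` with one run (replicate 1) per sample.
#' @export
average_replicates <- function(table) {
  first <- !duplicated(table$runs$sample_id)
  samples <- table$runs$sample_id[first]
  out <- matrix(NA_real_, nrow(table$intensities), length(samples))
  for (j in seq_along(samples)) {
    cols <- table$runs$sample_id == samples[j]
    m <- rowMeans(table$intensities[, cols, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[, j] <- m
  }
  feature_table(out, mz = table$features$mz, rt = table$features$rt,
                sample_id = samples, replicate = rep(1L, length(samples)),
                feature_id = table$features$feature_id,
                group = table$runs$group[first])
}

#' Run the full replicate-QC cascade
#'
#' Detection filter, CV filter, then replicate averaging, returning the
#' analysis-ready table and a consolidated report.
#'
#' @inheritParams cv_filter
#' @param min_fraction detection fraction passed to [detection_filter()].
#' @return list with `table` (filtered and replicate-averaged), `report`.
#' @export
qc_filter <- function(table, min_fraction = 1.0, max_cv_pct = 10,
                      aggregate = c("median", "mean"),
                      sd_convention = c("sample", "population")) {
  n_in <- nrow(table$intensities)
  det <- detection_filter(table, min_fraction)
  res <- cv_filter(det, max_cv_pct, aggregate, sd_convention)
  res$report$n_input_features <- n_in
  res$report$n_detected_all <- nrow(det$intensities)
  res$report$parameters$min_fraction <- min_fraction
  list(table = average_replicates(res$table), report = res$report)
}
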