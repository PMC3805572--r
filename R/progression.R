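#' Estimate an off-medication motor score from an on-medication exam
#'
#' When a medication-withdrawn ("off") exam is unavailable, the off score
#' is estimated by adding to the patient's on-exam score the difference of
#' the whole study population's mean off- and mean on-scores. Estimates
#' below zero are clamped to zero with a warning, since UPDRS motor scores
#' are nonnegative.
#'
#' @param on_score on-exam motor score(s), points.
#' @param population_mean_off,population_mean_on population means, points.
#' @return estimated off score(s), points.
#' @export
estimate_off_score <- function(on_score, population_mean_off,
                               population_mean_on) {
  est <- on_score + (population_mean_off - population_mean_on)
  if (any(est < 0, na.rm = TRUE)) {
    warning("estimated off score below 0 clamped to 0")
    est <- pmax(est, 0)
  }
  est
}

#' Impute a missing UPDRS item
#'
#' The baseline value is carried forward when present (no change assumed
#' from baseline to follow-up); otherwise the population mean for that item
#' is used. Zero is a valid present value, not a missing one.
#'
#' @param baseline_item baseline item score(s), possibly `NA`.
#' @param population_item_mean population mean for the item.
#' @return imputed item score(s).
#' @export
impute_missing_item <- function(baseline_item, population_item_mean) {
  if (any(is.na(baseline_item) & is.na(population_item_mean)))
    stop("both baseline and population mean missing")
  ifelse(is.na(baseline_item), population_item_mean, baseline_item)
}

#' Annual rate of change in motor score
#'
#' The difference of the last follow-up and baseline motor scores divided
#' by the interval between exams in years (days / 365.25). Negative rates
#' are permitted unless `floor_zero` is set.
#'
#' @param baseline_score,followup_score motor scores, points.
#' @param baseline_date,followup_date exam dates (`Date` or parseable
#'   strings); follow-up must postdate baseline.
#' @param floor_zero clamp negative rates at 0 (default `FALSE`).
#' @return points per year.
#' @export
annual_rate <- function(baseline_score, followup_score,
                        baseline_date, followup_date, floor_zero = FALSE) {
  years <- as.numeric(difftime(as.Date(followup_date),
                               as.Date(baseline_date),
                               units = "days")) / 365.25
  if (any(years <= 0))
    stop("follow-up exam must postdate baseline exam")
  rate <- (followup_score - baseline_score) / years
  if (floor_zero) rate <- pmax(rate, 0)
  rate
}

#' Classify progression rates into rapid and slow
#'
#' Rapid progressors are subjects whose annual rate falls in the top
#' quartile of the rate distribution. The cut is the nearest-rank empirical
#' quantile: with `n` subjects the top `ceiling((1 - quartile) * n)` rates
#' define the cut value, and `rapid` means rate >= cut, so ties at the cut
#' break toward rapid. With 233 distinct rates and the default quartile
#' this yields 59 rapid subjects.
#'
#' @param rates numeric annual rates, optionally named by subject.
#' @param quartile classification quantile (default 0.75; rapid = above).
#' @param subject_id optional ids (defaults to names or indices).
#' @return data.frame with `subject_id`, `annual_rate`, `classification`
#'   (`rapid`/`slow`) and `quartile_cut`.
#' @export
classify_progression <- function(rates, quartile = 0.75,
                                 subject_id = NULL) {
  n <- length(rates)
  if (n < 4) stop("need at least 4 subjects to classify quartiles")
  if (is.null(subject_id))
    subject_id <- if (!is.null(names(rates))) names(rates)
                  else as.character(seq_len(n))
  k <- ceiling((1 - quartile) * n)
  cut <- sort(rates, decreasing = TRUE)[k]
  if (length(unique(rates)) == 1)
    warning("all rates tied: every subject classified rapid")
  data.frame(subject_id = subject_id,
             annual_rate = as.numeric(rates),
             classification = ifelse(rates >= cut, "rapid", "slow"),
             quartile_cut = cut,
             stringsAsFactors = FALSE)
}

#' Progression phenotype from exam records
#'
#' Computes per-subject annual UPDRS motor progression from longitudinal
#' exam records and classifies subjects into rapid (top-quartile) and slow
#' progressors. On-medication exams are first converted to estimated
#' off-scores via the population mean off/on difference
#' ([estimate_off_score()]). Each subject's rate uses the first (baseline)
#' and last follow-up exam.
#'
#' @param exams data.frame with columns `subject_id`, `exam_date`,
#'   `motor_score`, `off_state` (logical).
#' @param quartile see [classify_progression()].
#' @param floor_zero see [annual_rate()].
#' @return data.frame of per-subject results plus attributes
#'   `group_summary` (mean, sd, range per class) and `population_means`
#'   (mean off/on scores used for estimation).
#' @export
progression_phenotype <- function(exams, quartile = 0.75,
                                  floor_zero = FALSE) {
  need <- c("subject_id", "exam_date", "motor_score", "off_state")
  if (!all(need %in% names(exams)))
    stop("exams needs columns: ", paste(need, collapse = ", "))
  exams$exam_date <- as.Date(exams$exam_date)
  exams$off_state <- as.logical(exams$off_state)
  mean_off <- mean(exams$motor_score[exams$off_state])
  mean_on <- mean(exams$motor_score[!exams$off_state])
  score <- exams$motor_score
  if (any(!exams$off_state) && is.finite(mean_on))
    score[!exams$off_state] <- estimate_off_score(
      score[!exams$off_state], mean_off, mean_on)
  exams$score_off <- score

  per <- split(exams, exams$subject_id)
  usable <- vapply(per, nrow, integer(1)) >= 2
  if (any(!usable))
    warning(sum(!usable), " subject(s) with < 2 exams dropped")
  per <- per[usable]
  rates <- vapply(per, function(d) {
    d <- d[order(d$exam_date), ]
    annual_rate(d$score_off[1], d$score_off[nrow(d)],
                d$exam_date[1], d$exam_date[nrow(d)],
                floor_zero = floor_zero)
  }, numeric(1))

  res <- classify_progression(rates, quartile, subject_id = names(per))
  sm <- do.call(rbind, lapply(split(res$annual_rate, res$classification),
    function(v) data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
                           min = min(v), max = max(v))))
  attr(res, "group_summary") <- sm
  attr(res, "population_means") <- c(off = mean_off, on = mean_on)
  res
}

#' Read longitudinal exam records
#'
#' Delimited text with columns `subject_id`, `exam_date` (ISO dates),
#' `motor_score`, `off_state` (TRUE/FALSE or 0/1).
#'
#' @inheritParams read_sample_meta
#' @return data.frame of exam records.
#' @export
read_exam_records <- function(path, delim = c("auto", "tab", "comma")) {
  sep <- resolve_delim(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "exam_date", "motor_score", "off_state")
  if (!all(need %in% names(df)))
    stop("exam file needs columns: ", paste(need, collapse = ", "))
  df$exam_date <- as.Date(df$exam_date)
  df$off_state <- as.logical(df$off_state)
  df
}
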