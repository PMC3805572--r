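#' Single-point response-factor calibration
#'
#' From replicate intensities of a target ion measured in a reference
#' material of known concentration, the response factor is
#' `RF = ref_concentration / mean(ref_intensities)` (optionally blank
#' corrected), in concentration units per intensity unit. A single RF
#' measured in a pooled reference enables absolute quantification of the
#' whole cohort without re-analysis.
#'
#' @param ref_intensities replicate intensities of the target in the
#'   reference material (all > 0 after blank correction).
#' @param ref_concentration known concentration in the reference (nM).
#' @param blank intensity to subtract before averaging (default 0).
#' @return object of class `calibration_factor`: list with
#'   `response_factor`, `ref_concentration`, `ref_mean_intensity`.
#' @export
calibrate_rf <- function(ref_intensities, ref_concentration, blank = 0) {
  m <- mean(ref_intensities, na.rm = TRUE) - blank
  if (!is.finite(m) || m <= 0 || ref_concentration <= 0)
    stop("reference intensity and concentration must be positive")
  structure(list(response_factor = ref_concentration / m,
                 ref_concentration = ref_concentration,
                 ref_mean_intensity = m),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf(
    "calibration_factor: RF = %.6g per intensity unit (%g @ intensity %.6g)\n",
    x$response_factor, x$ref_concentration, x$ref_mean_intensity))
  invisible(x)
}

#' Quantify a feature against a single-point calibration
#'
#' Per-sample concentration = response factor times the average of that
#' sample's technical-replicate intensities (blank corrected and floored
#' at zero). A sample with all replicates missing yields a missing
#' concentration.
#'
#' @param sample_intensities samples-by-replicates matrix (or a list of
#'   replicate vectors, or a single vector of per-sample intensities).
#' @param cal a `calibration_factor`.
#' @param aggregate `"mean"` (default) or `"median"` across replicates.
#' @param blank intensity to subtract before scaling (default 0).
#' @return named numeric vector of concentrations.
#' @export
quantify_feature <- function(sample_intensities, cal,
                             aggregate = c("mean", "median"), blank = 0) {
  stopifnot(inherits(cal, "calibration_factor"))
  aggregate <- match.arg(aggregate)
  f <- if (aggregate == "mean") mean else stats::median
  agg <- if (is.list(sample_intensities)) {
    vapply(sample_intensities, function(v)
      if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE), numeric(1))
  } else if (is.matrix(sample_intensities)) {
    apply(sample_intensities, 1, function(v)
      if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE))
  } else {
    as.numeric(sample_intensities)
  }
  cal$response_factor * pmax(agg - blank, 0)
}

#' One-way ANOVA with Tukey post test
#'
#' Compares group mean concentrations with a one-way ANOVA F test and all
#' pairwise Tukey honest-significant-difference comparisons (studentized
#' range; the Tukey-Kramer generalization covers unequal group sizes).
#' Degenerate input with zero between- and within-group variation returns
#' `F = 0`, `p = 1` and all pairwise adjusted p = 1.
#'
#' @param concentrations numeric per-sample values.
#' @param groups group labels (>= 2 groups with >= 2 samples each).
#' @return object of class `quant_result`: list with `group_summary`
#'   (mean, sd, n per group), `anova_f`, `anova_p`, `tukey` (data.frame:
#'   comparison, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(concentrations, groups) {
  keep <- !is.na(concentrations)
  y <- concentrations[keep]
  g <- factor(as.character(groups)[keep])
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  gs <- do.call(rbind, lapply(split(y, g), function(v)
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))))
  gs <- cbind(group = rownames(gs), gs)
  rownames(gs) <- NULL

  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    pairs <- utils::combn(levels(g), 2)
    tk <- data.frame(comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
                     diff = 0, lwr = 0, upr = 0, p_adj = 1,
                     stringsAsFactors = FALSE)
    res <- list(group_summary = gs, anova_f = 0, anova_p = 1, tukey = tk)
    class(res) <- "quant_result"
    return(res)
  }

  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  tk_raw <- stats::TukeyHSD(fit)$g
  tk <- data.frame(comparison = rownames(tk_raw),
                   diff = tk_raw[, "diff"], lwr = tk_raw[, "lwr"],
                   upr = tk_raw[, "upr"], p_adj = tk_raw[, "p adj"],
                   stringsAsFactors = FALSE, row.names = NULL)
  res <- list(group_summary = gs,
              anova_f = an[["F value"]][1],
              anova_p = an[["Pr(>F)"]][1],
              tukey = tk)
  class(res) <- "quant_result"
  res
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("quant_result: one-way ANOVA F = %.3f, p = %.4g\n",
              x$anova_f, x$anova_p))
  print(x$group_summary, row.names = FALSE)
  cat("Tukey HSD:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Quantify a target feature across a cohort and compare groups
#'
#' Extracts one feature's replicate intensities from the table, applies a
#' single-point calibration, and runs the one-way ANOVA / Tukey group
#' comparison.
#'
#' @param table a `feature_table` with group labels attached (or `meta`
#'   supplied).
#' @param feature_id the target feature.
#' @param cal a `calibration_factor`.
#' @param meta optional sample metadata.
#' @inheritParams quantify_feature
#' @return a `quant_result` with an added `concentrations` element (named
#'   per-sample vector).
#' @export
quantify_target <- function(table, feature_id, cal, meta = NULL,
                            aggregate = c("mean", "median"), blank = 0) {
  if (!is.null(meta)) table <- attach_groups(table, meta)
  i <- match(feature_id, table$features$feature_id)
  if (is.na(i)) stop("unknown feature: ", feature_id)
  samples <- unique(table$runs$sample_id)
  reps <- lapply(samples, function(s)
    table$intensities[i, table$runs$sample_id == s])
  conc <- stats::setNames(quantify_feature(reps, cal, aggregate, blank),
                          samples)
  grp <- table$runs$group[match(samples, table$runs$sample_id)]
  res <- anova_tukey(conc, grp)
  res$concentrations <- conc
  res
}
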