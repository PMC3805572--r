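#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline is meant for: a 100-serum
#' cohort (20 controls, 41 slow and 39 rapid progressors) analysed in
#' triplicate, features on an m/z scan range of 85-850, a small set of
#' features shifted in the rapid group, and a handful of block-correlated
#' metabolite modules on top of independent log10-normal baselines.
#'
#' @param n_features number of m/z features.
#' @param n_per_group named counts for `control`, `slow`, `rapid` samples.
#' @param n_replicates technical replicates per sample (triplicate default).
#' @param n_effect_features number of features with a planted group shift.
#' @param effect_size standardized mean difference on the log10 scale.
#' @param effect_group group receiving the shift.
#' @param n_modules,module_size planted correlation modules.
#' @param within_module_r target pairwise Pearson correlation inside a
#'   module (latent-factor construction, exact in expectation).
#' @param between_module_r target correlation between the latent factors of
#'   different modules (default 0: independent modules). A nonzero value
#'   gives the eigengene network off-diagonal structure, which is what the
#'   module-preservation statistic measures; with independent modules both
#'   cohorts' eigengene networks sit near 0.5 and there is nothing to
#'   preserve or destroy.
#' @param replicate_cv_pct target percent coefficient of variation of
#'   technical replicates on the raw intensity scale.
#' @param missing_rate probability that any single cell is missing
#'   (uniform at random, applied after noise). The default 0.0013 makes
#'   roughly two thirds of features complete across 300 runs, matching the
#'   detected-in-all fraction typical of triplicate serum extractions.
#' @param mz_range,rt_range uniform ranges for m/z (Da) and retention time
#'   (seconds).
#' @param base_log_mean,base_log_sd baseline log10-intensity model:
#'   per-feature means drawn `N(base_log_mean, 1)`, within-feature SD
#'   `base_log_sd`.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_features = 1000,
                         n_per_group = c(control = 20, slow = 41, rapid = 39),
                         n_replicates = 3,
                         n_effect_features = 10,
                         effect_size = 1.5,
                         effect_group = "rapid",
                         n_modules = 4,
                         module_size = 25,
                         within_module_r = 0.7,
                         between_module_r = 0,
                         replicate_cv_pct = 10,
                         missing_rate = 0.0013,
                         mz_range = c(85, 850),
                         rt_range = c(30, 600),
                         base_log_mean = 5,
                         base_log_sd = 0.5,
                         seed = 17) {
  cfg <- as.list(environment())
  if (cfg$n_effect_features + cfg$n_modules * cfg$module_size > cfg$n_features)
    stop("infeasible config: planted effect and module features exceed n_features")
  if (cfg$within_module_r < 0 || cfg$within_module_r >= 1)
    stop("within_module_r must lie in [0, 1)")
  if (cfg$between_module_r < 0 || cfg$between_module_r >= 1)
    stop("between_module_r must lie in [0, 1)")
  if (cfg$replicate_cv_pct < 0) stop("replicate_cv_pct must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (is.null(names(cfg$n_per_group)))
    names(cfg$n_per_group) <- c("control", "slow", "rapid")
  if (!cfg$effect_group %in% names(cfg$n_per_group))
    stop("effect_group not among group names")
  structure(cfg, class = "synth_config")
}

#' Simulate a synthetic LC-MS cohort with known ground truth
#'
#' Per-sample true log10 intensities are drawn from a feature-wise normal
#' baseline. Module members share a latent factor
#' `z = sqrt(r) * f + sqrt(1 - r) * eps`, which gives pairwise correlation
#' exactly `r` in expectation. Effect features are shifted by
#' `effect_size` within-feature SDs in the designated group. Each technical
#' replicate observes the true intensity times multiplicative log-normal
#' noise whose sigma is set from the target percent CV via
#' `sigma = sqrt(log(1 + (cv/100)^2))`, the exact CV of a log-normal on the
#' raw intensity scale. Missing cells are then dropped uniformly at random.
#'
#' @param config a [synth_config()].
#' @return list with elements `table` (a [feature_table()] with group
#'   labels attached), `meta` (sample metadata data.frame), and `truth`
#'   (class `synth_truth`: `effect_feature_ids`, `module_labels` named by
#'   feature with 0 = background, and `params`).
#' @export
simulate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_features
  groups <- rep(names(config$n_per_group), config$n_per_group)
  ns <- length(groups)
  r <- config$n_replicates
  sample_id <- sprintf("S%03d", seq_len(ns))

  ids <- sprintf("F%05d", seq_len(n))
  perm <- sample.int(n)
  eff_idx <- perm[seq_len(config$n_effect_features)]
  module_labels <- integer(n)
  pos <- config$n_effect_features
  for (k in seq_len(config$n_modules)) {
    module_labels[perm[pos + seq_len(config$module_size)]] <- k
    pos <- pos + config$module_size
  }

  z <- matrix(stats::rnorm(n * ns), n, ns)
  rho <- config$within_module_r
  b <- config$between_module_r
  g_common <- stats::rnorm(ns)
  for (k in seq_len(config$n_modules)) {
    members <- which(module_labels == k)
    # factor correlation between modules k != l is exactly b
    f <- sqrt(b) * g_common + sqrt(1 - b) * stats::rnorm(ns)
    z[members, ] <- sqrt(rho) * rep(f, each = length(members)) +
      sqrt(1 - rho) * z[members, ]
  }

  mu <- stats::rnorm(n, config$base_log_mean, 1)
  log_true <- mu + config$base_log_sd * z
  in_group <- groups == config$effect_group
  log_true[eff_idx, in_group] <- log_true[eff_idx, in_group] +
    config$effect_size * config$base_log_sd
  true_int <- 10^log_true

  sigma <- sqrt(log1p((config$replicate_cv_pct / 100)^2))
  ints <- matrix(NA_real_, n, ns * r)
  run_sample <- rep(sample_id, each = r)
  run_rep <- rep(seq_len(r), times = ns)
  run_group <- rep(groups, each = r)
  for (s in seq_len(ns)) {
    noise <- matrix(exp(sigma * stats::rnorm(n * r)), n, r)
    ints[, (s - 1) * r + seq_len(r)] <- true_int[, s] * noise
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(ints)) < config$missing_rate
    ints[drop] <- NA_real_
  }

  mz <- stats::runif(n, config$mz_range[1], config$mz_range[2])
  rt <- stats::runif(n, config$rt_range[1], config$rt_range[2])

  tab <- feature_table(ints, mz = mz, rt = rt, sample_id = run_sample,
                       replicate = run_rep, feature_id = ids,
                       group = run_group)
  meta <- data.frame(sample_id = sample_id, group = groups,
                     stringsAsFactors = FALSE)
  truth <- structure(list(effect_feature_ids = ids[eff_idx],
                          module_labels = stats::setNames(module_labels, ids),
                          params = config),
                     class = "synth_truth")
  list(table = tab, meta = meta, truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("synth_truth: %d effect features, %d modules of size %d\n",
              length(x$effect_feature_ids), x$params$n_modules,
              x$params$module_size))
  invisible(x)
}

#' Shift designated features in one group
#'
#' Multiplies the named group's intensities of the designated features by
#' `10^(effect_size * sd_log10)`, where `sd_log10` is that feature's SD of
#' log10 intensity across all runs -- i.e. a shift of `effect_size`
#' standard deviations on the log scale. All other cells are untouched.
#'
#' @param table a `feature_table`.
#' @param feature_ids features to shift.
#' @param group group label receiving the shift (taken from the table's run
#'   metadata, or from `meta` when supplied).
#' @param effect_size standardized shift; 0 leaves the table unchanged.
#' @param meta optional sample metadata to resolve groups.
#' @return the modified `feature_table`.
#' @export
inject_effect <- function(table, feature_ids, group, effect_size,
                          meta = NULL) {
  if (!is.null(meta)) table <- attach_groups(table, meta)
  idx <- match(feature_ids, table$features$feature_id)
  if (anyNA(idx))
    stop("unknown feature: ",
         paste(feature_ids[is.na(idx)], collapse = ", "))
  if (!length(idx) || effect_size == 0) return(table)
  in_group <- table$runs$group %in% group
  if (!any(in_group)) stop("unknown or absent group: ", group)
  for (i in idx) {
    v <- table$intensities[i, ]
    sd_log <- stats::sd(log10(v[!is.na(v) & v > 0]))
    if (!is.finite(sd_log)) next
    table$intensities[i, in_group] <-
      table$intensities[i, in_group] * 10^(effect_size * sd_log)
  }
  table
}
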