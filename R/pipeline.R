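#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a cohort, applies replicate QC, runs the slow-vs-rapid
#' metabolome-wide FDR analysis, OSC-corrected PLS-DA with PCLS selection
#' and the FDR/PCLS intersection, builds the correlation network on the
#' reference (slow) cohort and scores module preservation in the test
#' (rapid) cohort, and quantifies a target feature against a single-point
#' calibration. Every stage's result table can be written to `out_dir`.
#'
#' @param config a [synth_config()]; its seed governs all randomness.
#' @param groups the two groups compared (default slow vs rapid).
#' @param max_cv_pct replicate-CV threshold for the QC stage. The default
#'   `Inf` applies the detection filter only, feeding the complete-feature
#'   set to every downstream stage; set 10 to restrict all stages to the
#'   high-precision CV-filtered set instead.
#' @param q target FDR (default 0.2).
#' @param n_pred,n_osc chemometric components (defaults 2 and 1).
#' @param pcls_corr,pcls_top,pcls_fraction_of PCLS parameters (defaults
#'   0.95 / 0.01 / `"all"`; see [pcls_select()]).
#' @param beta,cut_height,min_size network parameters.
#' @param ref_concentration calibration concentration (nM) of the target
#'   in the reference material (default 10.1).
#' @param response_factor known response factor used to back-calculate the
#'   reference intensity for the synthetic calibration record (default
#'   2.13e-5 nM per intensity unit).
#' @param out_dir optional directory for delimited result tables.
#' @return list with `table`, `meta`, `truth`, `qc`, `univariate`,
#'   `manhattan`, `opls`, `pcls`, `venn`, `network`, `preservation`,
#'   `quant`.
#' @export
run_pipeline <- function(config = synth_config(),
                         groups = c("slow", "rapid"),
                         max_cv_pct = Inf, q = 0.2,
                         n_pred = 2, n_osc = 1,
                         pcls_corr = 0.95, pcls_top = 0.01,
                         pcls_fraction_of = "all",
                         beta = 6, cut_height = 0.99, min_size = 10,
                         ref_concentration = 10.1,
                         response_factor = 2.13e-5,
                         out_dir = NULL) {
  sim <- simulate_cohort(config)
  message(sprintf("pipeline: seed=%d, %d features x %d samples x %d replicates",
                  config$seed, config$n_features,
                  sum(config$n_per_group), config$n_replicates))
  qc <- qc_filter(sim$table, min_fraction = 1, max_cv_pct = max_cv_pct)
  tab <- qc$table

  uni <- univariate_analysis(tab, sim$meta, groups[1], groups[2], q = q)
  man <- manhattan_data(uni, q = q)

  model <- oplsda(tab, sim$meta, groups, n_pred = n_pred, n_osc = n_osc)
  pcls <- pcls_select(model, corr_threshold = pcls_corr,
                      top_fraction = pcls_top,
                      fraction_of = pcls_fraction_of)
  venn <- intersect_selections(
    uni$feature_id[uni$significant_at_q],
    pcls$feature_id[pcls$selected])

  ref_samples <- sim$meta$sample_id[sim$meta$group == groups[1]]
  test_samples <- sim$meta$sample_id[sim$meta$group == groups[2]]
  X <- sample_matrix(tab)
  ref_X <- X[ref_samples, , drop = FALSE]
  test_X <- X[test_samples, , drop = FALSE]
  A <- adjacency(ref_X, beta = beta)
  part <- detect_modules(topological_overlap(A),
                         min_size = min_size, cut_height = cut_height)
  pres <- if (part$n_modules >= 2)
    module_preservation(ref_X, test_X, part)
  else NULL

  target <- if (length(venn$both)) venn$both[1]
            else sim$truth$effect_feature_ids[1]
  cal <- calibrate_rf(ref_concentration / response_factor,
                      ref_concentration)
  quant <- quantify_target(sim$table, target, cal, meta = sim$meta)

  res <- list(table = tab, meta = sim$meta, truth = sim$truth,
              qc = qc$report, univariate = uni, manhattan = man,
              opls = model, pcls = pcls, venn = venn,
              network = list(partition = part),
              preservation = pres, quant = quant, target = target)
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write every pipeline result table to a directory
#'
#' @param res a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_feature_table(res$table, fp("feature_table_qc.tsv"))
  write_sample_meta(res$meta, fp("sample_meta.tsv"))
  write_tsv(data.frame(feature_id = names(res$truth$module_labels),
                       module = as.integer(res$truth$module_labels),
                       effect = names(res$truth$module_labels) %in%
                         res$truth$effect_feature_ids),
            fp("truth.tsv"))
  write_tsv(as.data.frame(res$univariate), fp("univariate.tsv"))
  man <- as.data.frame(res$manhattan)
  write_tsv(man, fp("manhattan.tsv"))
  write_tsv(res$opls$score_plot, fp("opls_scores.tsv"))
  write_tsv(data.frame(feature_id = res$opls$feature_id,
                       p1 = res$opls$loadings[, 1],
                       p2 = if (ncol(res$opls$loadings) > 1)
                              res$opls$loadings[, 2] else NA_real_),
            fp("opls_loadings.tsv"))
  write_tsv(as.data.frame(res$pcls), fp("pcls.tsv"))
  write_tsv(data.frame(set = names(res$venn$counts),
                       count = as.integer(res$venn$counts)),
            fp("venn_counts.tsv"))
  write_tsv(data.frame(feature_id = names(res$network$partition$labels),
                       module = as.integer(res$network$partition$labels)),
            fp("modules.tsv"))
  if (!is.null(res$preservation)) {
    write_tsv(as.data.frame(res$preservation$P), fp("preservation_matrix.tsv"))
    write_tsv(data.frame(module = names(res$preservation$preservation),
                         mean_preservation = res$preservation$preservation),
              fp("preservation_means.tsv"))
  }
  write_tsv(data.frame(sample_id = names(res$quant$concentrations),
                       concentration_nM = res$quant$concentrations),
            fp("concentrations.tsv"))
  write_tsv(res$quant$tukey, fp("tukey.tsv"))
  invisible(out_dir)
}
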