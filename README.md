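# metaboprog

Serum-metabolomics analysis of disease motor-progression phenotypes.

`metaboprog` is an R package for untargeted LC-MS feature-table analysis
aimed at a specific clinical question: can serum metabolic profiles,
measured early in disease, distinguish patients whose motor symptoms will
progress slowly from those who will progress rapidly? It implements the
complete statistical pipeline for that design — and, because such studies
rarely deposit raw data, a synthetic cohort generator with planted ground
truth so the whole pipeline can be exercised and scored end to end.

## What it computes

- **Progression phenotyping.** Annual UPDRS motor-score change
  `(last follow-up − baseline) / years`, with off-medication score
  estimation (`on + (mean_off − mean_on)`), missing-item imputation, and
  top-quartile classification into rapid vs slow progressors
  (nearest-rank cut, `ceiling(n/4)` rapid; 233 distinct rates give 59).
- **Replicate QC.** Detection-in-all-runs filtering, per-feature
  technical-replicate %CV (`100·sd/mean`, median across samples) and the
  CV ≤ 10% precision filter, replicate averaging.
- **Metabolome-wide testing.** Feature-wise Welch t-tests on log10
  intensities with Benjamini–Hochberg FDR control at `q = 0.2` and
  Manhattan-plot data (`−log10 p` with the FDR line).
- **Chemometrics.** Autoscaling, PCA, orthogonal signal correction (OSC)
  removing class-orthogonal variation, NIPALS PLS-DA, and PCLS — feature
  selection by combined correlation `R = sqrt(r1² + r2²)` to the first
  two discriminant scores — plus the FDR ∩ PCLS intersection with Venn
  counts.
- **Correlation networks.** Soft-threshold adjacency `|r|^β`, topological
  overlap (TOM), average-linkage module detection with a static tree cut,
  module eigengenes, eigengene networks `A = (1 + cor)/2`, and module
  preservation between cohorts `P = 1 − |A_ref − A_test|` with per-module
  column means.
- **Absolute quantification.** Single-point response-factor calibration
  (`RF = conc / mean intensity`; the worked calibration reproduces
  `RF = 2.13e-5` and 10.1 nM), per-sample concentrations, one-way ANOVA
  with Tukey HSD.
- **Synthetic cohorts.** Log10-normal intensities, planted group shifts,
  latent-factor correlation modules, replicate CV noise, uniform
  missingness — all seeded and returned with ground truth.

## Worked example

```r
library(metaboprog)

cfg <- synth_config(seed = 17)      # 1,000 features, 100 samples, triplicate
sim <- simulate_cohort(cfg)
qc  <- qc_filter(sim$table, min_fraction = 1, max_cv_pct = 10)
qc$report
#> qc_report: 1000 features in; 660 detected in all runs; 658 pass CV <= 10%
#>   (median of per-sample CVs, sample SD)

uni <- univariate_analysis(qc$table, sim$meta, "slow", "rapid", q = 0.2)
sum(uni$significant_at_q)
#> [1] 12

model <- oplsda(qc$table, sim$meta, c("slow", "rapid"))
model
#> opls_model: 2 predictive component(s), 1 OSC component(s)
#> r2x: 0.019 0.021  r2y: 0.932 0.053

pcls <- pcls_select(model, corr_threshold = 0.5, top_fraction = 0.05)
venn <- intersect_selections(uni$feature_id[uni$significant_at_q],
                             pcls$feature_id[pcls$selected])
venn$counts
#> a_only   both b_only
#>      5      7      7

cal <- calibrate_rf(474178.4, 10.1)   # reference intensity, 10.1 nM
cal
#> calibration_factor: RF = 2.13e-05 per intensity unit (10.1 @ intensity 474178)
quant <- quantify_target(sim$table, venn$both[1], cal, meta = sim$meta)
quant$anova_p
#> [1] 0.0006073
```

Reading the output: 660 of 1,000 simulated features are detected in every
run and 658 of those pass the precision filter; 12 features clear the
metabolome-wide FDR threshold, 7 of which are also selected by PCLS
(the `both` Venn cell) — on this seed, all 7 are planted effect features
(`sim$truth$effect_feature_ids`). The one-hot PLS-DA response is almost
fully explained by the first component (`r2y = 0.93`), and the quantified
target differs between groups (ANOVA p ≈ 6e-4, with Tukey HSD localizing
the slow-vs-rapid contrast).

The same stages are scriptable from a shell through the thin CLI wrapper:

```sh
Rscript inst/cli/metaboprog.R simulate --seed 17 --out-dir out/
Rscript inst/cli/metaboprog.R qc --table out/feature_table.tsv --max-cv 10 --out-dir out/
Rscript inst/cli/metaboprog.R run-all --seed 17 --out-dir out/
```

## Package layout

- `R/feature_table.R` — the `feature_table` container and delimited IO
- `R/synthetic.R` — cohort generator and ground truth
- `R/qc.R` — detection/CV filters and replicate averaging
- `R/progression.R` — UPDRS rates and top-quartile classification
- `R/univariate.R` — t-tests, BH FDR, Manhattan data
- `R/chemometrics.R` — autoscaling, PCA, OSC, PLS-DA, PCLS
- `R/network.R` — adjacency, TOM, modules, eigengenes, preservation
- `R/quantify.R` — response-factor calibration, ANOVA/Tukey
- `R/pipeline.R`, `R/cli.R` — end-to-end runner and CLI dispatcher
- `vignettes/metaboprog-methods.Rmd` — models, assumptions, design choices
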