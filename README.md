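# sexmetab

Sex-stratified metabolite–brain association analysis for neurodegeneration
cohorts.

Men and women differ in the prevalence, presentation and progression of
Alzheimer's disease, and blood metabolomics is one of the few windows onto
the systemic side of that process. `sexmetab` implements, as a tested and
reusable R pipeline, the full analysis needed to ask whether the
association between circulating metabolites and structural brain decline
differs between the sexes:

1. **Metabolomics QC** for two platform styles — a targeted panel with
   plates, assay replicates and limits of detection (LOD), and an
   NMR-style panel with QC tags: missingness filters (analytes at ≥ 20%,
   participants at > 40%), cross-plate mean normalization, replicate
   CV/ICC filters (CV > 20%, ICC < 65%), replicate averaging, half-LOD or
   half-minimum imputation of left-censored values,
   add-1/log2/z-score/winsorize transformation, medication
   residualization with backward selection, and Mahalanobis multivariate
   outlier removal at chi-square *P* < 0.001.
2. **Brain phenotype reduction**: six FreeSurfer-style segment volumes
   (ventricles, hippocampus, entorhinal, fusiform, middle temporal,
   whole brain) divided by intracranial volume (log for the ventricle
   ratio), then a NIPALS PLS-DA against the consolidated CN/MCI/AD
   diagnosis, giving orthogonal "brain component" scores, per-component
   variance explained, and VIP importance per segment.
3. **Metabolite modules**: unsigned weighted correlation network
   (similarity = |r|, adjacency = |r|^β with β = 10 by default),
   topological overlap matrix, average-linkage clustering with an
   adaptive branch cut honoring a minimum module size, eigen-metabolite
   summaries (first principal component per module), module membership
   (kME), and merging of modules with eigen correlation r > 0.9.
4. **Sex-difference detection**: per-sex OLS of each metabolite/module
   on the brain components plus age, education and APOE ε4, and two
   frameworks —

   the heterogeneity test

   &nbsp;&nbsp;&nbsp;&nbsp;Z<sub>diff</sub> = (β<sub>f</sub> − β<sub>m</sub>) / √(se<sub>f</sub>² + se<sub>m</sub>²),

   the inverse-variance overall test

   &nbsp;&nbsp;&nbsp;&nbsp;Z<sub>overall</sub> = (β<sub>f</sub>/se<sub>f</sub>² + β<sub>m</sub>/se<sub>m</sub>²) / √(1/se<sub>f</sub>² + 1/se<sub>m</sub>²),

   a two-fold screen (sex-difference test Bonferroni-corrected over all
   associations, and over the subset with overall *P* < 10⁻⁵), and a
   criterion-based classification into *homogeneous*, *heterogeneous*,
   *sex-specific* or *none*, with module-level Bonferroni 0.05/(M·C) and
   single-metabolite Bonferroni 0.05/(I·C) where I is the eigenvalue-based
   effective number of independent tests.

Because real cohorts of this kind are access-restricted, the package
ships a **synthetic cohort generator** (`sim_config()`,
`generate_cohort()`) with a known ground truth — block-correlated
metabolite panels from a latent-factor model, multiplicative plate
effects, LOD censoring, duplicate/triplicate replicates, diagnosis-linked
atrophy with ventricular enlargement, and per-sex metabolite–brain
effects — so every stage has a recoverable answer and the whole pipeline
is validated end to end.

## Worked example

```r
library(sexmetab)
cfg <- pipeline_config(
  sim = sim_config(n_participants = 1200, sex_ratio = 0.5, seed = 42),
  output_dir = "sexmetab_run")
res <- run_pipeline(cfg)

round(res$model$x_variance, 3)
#> [1] 0.546 0.114 0.119 0.075 0.081
round(res$model$vip, 2)
#>  ventricles hippocampus  entorhinal    fusiform midtemporal  wholebrain
#>        1.23        1.11        1.05        0.81        0.86        0.87
table(res$partition$labels)
#>      blue     brown      grey turquoise
#>        15        10        20        15

r <- res$associations
r[r$unit_type == "module" & r$component == "C1",
  c("unit", "beta_f", "beta_m", "p_diff", "arnold_category")]
#>       unit  beta_f  beta_m   p_diff arnold_category
#>  turquoise -0.4391 -0.1020 2.43e-09    sex-specific
#>       blue -0.2630 -0.2235 4.95e-01     homogeneous
#>      brown -0.0466 -0.0354 8.50e-01            none
```

The default generator plants three metabolite modules. The first
(recovered here as `turquoise`) loads on the disease-severity brain
factor with a female coefficient of 0.6 and a male coefficient of 0.2:
the stratified fit recovers a much stronger female effect on brain
component 1 and a tiny sex-difference P-value. In this particular
replicate the male arm misses its Bonferroni threshold, so the
classification lands on *sex-specific* (Bonferroni-significant in
exactly one sex with significant Z<sub>diff</sub>) rather than
*heterogeneous*; across seeds, the heterogeneous label dominates. The
second module (`blue`) has the same loading (0.3) in both sexes —
strongly associated in both strata, non-significant Z<sub>diff</sub>,
hence *homogeneous*. The third (`brown`) has no brain association at
all and stays *none*.

Artifacts (`clean_matrix.tsv`, `scores.tsv`, `modules.tsv`,
`eigens.tsv`, `associations.tsv`, `qc_report.json`, `manifest.json`, …)
are written to the output directory; `inst/cli/sexmetab.R` exposes the
same flow as a command line (`simulate`, `all`, `report`).

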