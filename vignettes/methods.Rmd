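---
title: "Methods: sex differences in metabolite–brain associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex differences in metabolite–brain associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model behind `sexmetab`, the
parameters that matter, the design choices made where the protocol was
genuinely open, and what the synthetic-data validation does and does not
establish.

## The question and the model

The pipeline asks whether the linear association between a blood
metabolite (or a module of co-varying metabolites) and a structural
brain phenotype differs between women and men. Within each sex stratum
it fits ordinary least squares

$$ y_i \;=\; \alpha + \sum_c \beta_c\, t_{ic} + \gamma_1\,\mathrm{age}_i
   + \gamma_2\,\mathrm{edu}_i + \gamma_3\,\mathrm{APOE4}_i
   + \varepsilon_i, $$

where $y$ is the transformed metabolite (or eigen-metabolite) and
$t_{ic}$ are brain component scores. Sex differences are then assessed
two ways:

* the **heterogeneity test**
  $Z_{\mathrm{diff}} = (\beta_f - \beta_m)/\sqrt{se_f^2 + se_m^2}$,
  referred to the standard normal, applied either Bonferroni-corrected
  over all associations or over the subset passing the overall filter
  $P_{\mathrm{overall}} < 10^{-5}$, where
  $Z_{\mathrm{overall}}$ is the fixed-effects inverse-variance
  combination of the two strata;
* a **criterion-based classification**: an association is selected if
  it is Bonferroni-significant in the pooled cohort, or in at least one
  sex, or nominally significant in one sex with $P_{\mathrm{diff}}<
  0.05$; selected associations are *sex-specific* when exactly one
  stratum is Bonferroni-significant and $P_{\mathrm{diff}}<0.05$,
  otherwise *heterogeneous* ($P_{\mathrm{diff}}<0.05$) or *homogeneous*.

Module-level tests use $\alpha = 0.05/(M\!\cdot\!C)$; single-metabolite
tests use $\alpha = 0.05/(I\!\cdot\!C)$ with $I$ the eigenvalue-based
effective number of independent tests
($I = \sum_i [\mathbf{1}(\lambda_i \ge 1) + (\lambda_i -
\lfloor\lambda_i\rfloor)]$ over the eigenvalues of the metabolite
correlation matrix).

A subtlety worth recording: under the null, $P_{\mathrm{diff}}$ and
$\min(P_f, P_m)$ are strongly positively dependent — an opposite-sign
fluctuation of the two stratified estimates inflates both — so the
nominal selection rate of the third criterion is about 0.025, not the
independence product $0.0975 \times 0.05 \approx 0.005$. The acceptance
suite computes this nominal rate by Monte Carlo from the null sampling
distribution instead of assuming independence.

## Preprocessing protocol

The targeted-platform order is fixed: (1) missingness filters —
analytes with $\ge 20\%$ missing (inclusive bound), then participants
with $> 40\%$ missing (strict); (2) cross-plate mean normalization —
each plate's values are multiplied by grand mean / plate mean, a
multiplicative form chosen because it preserves positivity for the
later log transform and is idempotent; (3) replicate quality — CV per
metabolite is the mean over replicate groups of group SD / group mean,
ICC is the one-way random-effects ANOVA estimate
$(MS_B - MS_W)/(MS_B + (k_0-1)MS_W)$ with the unbalanced-design
effective group size $k_0$; analytes with CV $> 0.20$ or ICC $< 0.65$
are removed; (4) non-fasting participants removed; (5) replicates
averaged; (6) bespoke assay exclusions via a configurable manual list
(not hard-coded analyte names); (7) half-LOD imputation per metabolite
per plate; (8) add 1 (some LODs are zero), log2, z-score with the
population SD, winsorize at $\pm 3$; (9) medication residualization;
(10) Mahalanobis outlier removal at $\chi^2$ tail $P < 0.001$. The
NMR-style branch differs as the protocol does: QC-tagged missing values
other than "below limit of quantification" remove the participant,
imputation is half the minimum observed value, and no winsorizing is
applied by default.

Open points resolved here, each applied once in the stated order:
z-scoring is not re-applied after winsorizing or after medication
residualization (so residualized columns may slightly exceed $\pm 3$;
the $[-3,3]$ guarantee refers to the transformation step), and the
outlier screen runs on the full transformed matrix, which requires more
participants than analytes — when $p \ge n$ the operation errors rather
than silently regularizing.

## Brain phenotypes

Segment volumes are divided by intracranial volume; the ventricle ratio
is log-transformed (its distribution is strongly right-skewed because
ventricles *enlarge* with disease). The six-level diagnosis is
consolidated (CN/SMC → CN; EMCI/MCI/LMCI → MCI; AD → AD) and dummy
coded. The PLS-DA is a NIPALS PLS2: predictors autoscaled (otherwise
the whole-brain volume's numeric magnitude dominates), dummy Y centered
but not scaled, deflation on X only — which makes score vectors exactly
orthogonal and is covered by an eigen-decomposition oracle in the
tests. Variance explained is reported on X (the brain volumes), with
Y-variance kept for the VIP weights
$\mathrm{VIP}_j = \sqrt{p \sum_a SSY_a (w_{ja}/\lVert w_a\rVert)^2 /
\sum_a SSY_a}$. Component selection takes the smallest leading prefix
reaching the 0.95 cumulative X-variance target; when unreachable, all
requested components are returned with a warning — on this generator's
six volumes the cumulative share at five components is typically just
below 0.95, so the warning is the expected path, mirroring the fact
that printed per-component percentages in real analyses of this design
round to slightly less than their stated total.

## Metabolite networks

The network is unsigned: similarity $|r|$, adjacency $|r|^\beta$ with
$\beta = 10$ by default, and topological overlap
$\mathrm{TOM}_{ij} = (\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}) /
(\min(k_i,k_j) + 1 - a_{ij})$. Clustering is average-linkage (the WGCNA
convention) on $1-\mathrm{TOM}$.

For the branch cut, this package deviates from the published top-down
"tree" algorithm in favor of a simpler adaptive rule: branches are read
off at height $h_{\max} - g\,(h_{\max}-h_{\min})$ of the tree's own
merge-height distribution ($g = 0.15$), clusters below the minimum size
become grey. The reason is robustness across soft powers: at
$\beta = 10$ a $\rho = 0.6$ block has within-block TOM dissimilarities
around 0.994 and between-block merges at 0.9999, so any rule based on
absolute heights or parent–child gaps fails, while the height-range
normalization handles both this regime and strong ($\rho = 0.8$)
blocks. The cost is that modules of very different internal tightness
in one panel may not all be resolved at a single cut; a fixed
`cut_height` fallback is provided. Module size floors (5 targeted, 10
NMR-style) and the grey module for unassigned analytes follow the
protocol; grey metabolites still flow into single-metabolite testing.

Eigen-metabolites are first principal components of the scaled member
profiles, rescaled to unit variance, sign-aligned to the module mean
profile (removing PC sign ambiguity); module membership is the Pearson
correlation with the own-module eigen-metabolite. Modules whose
eigen-metabolites correlate above $r = 0.9$ (strict) are merged
iteratively — highest pair first, eigen recomputed after every merge,
ties broken by the alphabetically smallest label pair.

## The synthetic cohort: what it emulates

`generate_cohort()` draws from a latent-factor world chosen once:

* **Latent brain factors** $b_1,\dots,b_5$; $b_1$ is standardized
  disease severity (diagnosis level plus noise), the rest are
  independent standard normals with small fixed loadings on the
  segments.
* **Brain volumes**: segment $= \mathrm{base}_j \cdot
  (\mathrm{ICV}/1.5\cdot 10^6) \cdot (1 + e_j\,\mathrm{sev} +
  \text{structure} + \text{noise})$, with per-step effects
  (ventricles $+0.25$, hippocampus $-0.10$, entorhinal $-0.12$,
  fusiform $-0.05$, mid-temporal $-0.07$, whole brain $-0.035$) on the
  order of published atrophy contrasts, and segment noise SDs of
  3–12%.
* **Metabolites**: module members are
  $\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$, so the expected
  within-module correlation is exactly $\rho$; the module latent $f$
  loads on the brain factors with per-sex coefficients. Concentrations
  are $\exp(z)\cdot s_k$ with $s_k$ log-uniform in $[1, 100]$ assay
  units — bounded below by 1 so the protocol's add-1 constant does not
  crush the signal; multiplicative per-metabolite per-plate batch
  effects (log-SD 0.1); left-censoring at the per-plate empirical
  `lod_quantile` (default 2%); 10% of participants replicated (every
  fifth as a triplicate) with technical noise SD 0.1 z-units.
* **Default effect structure**: module 1 loads on $b_1$ with 0.6
  (female) vs 0.2 (male) — a sex gap of 0.4 with both sexes carrying a
  Bonferroni-detectable signal at $n = 600$/sex, which is what makes
  the expected classification *heterogeneous* rather than
  *sex-specific*; module 2 loads 0.3 in both sexes (homogeneous);
  module 3 loads nothing (null). All three use $\rho = 0.6$, within the
  range reported for co-regulated lipid panels.
* **Outliers**: `inject_outliers()` shifts each chosen participant by
  the stated magnitude along its *own* random unit direction —
  per-outlier directions, because a shared direction makes the
  outliers a cluster that inflates the sample covariance along itself
  and masks the Mahalanobis screen.

Deliberately not emulated: assay chemistry, longitudinal visits,
realistic joint covariate distributions beyond marginal ranges, and
platform-specific analyte identities. A green end-to-end test therefore
establishes that the statistical machinery recovers planted structure
under the stated noise model — not that the pipeline reproduces any
particular cohort's biology.

## Numerical choices and edge cases

* z-scoring uses the population SD (denominator $n$), matching the
  worked z-score examples the tests freeze.
* Component scores are standardized to unit variance before
  association, so βs read as effect per SD of brain component and the
  generator's loadings are recoverable on their own scale.
* P-values for stratified βs use the $t$ distribution with residual
  degrees of freedom; $Z_{\mathrm{diff}}$ and $Z_{\mathrm{overall}}$
  use the normal, as their definitions state.
* The pooled-cohort test for the first selection criterion is a pooled
  regression with sex as an additional covariate (the convention of the
  criterion's source), kept distinct from $Z_{\mathrm{overall}}$; both
  are computed.
* APOE ε4 enters as a linear allele count (0/1/2).
* Degenerate trees (all merge heights equal) collapse to one module;
  a singular covariance in the Mahalanobis screen, a constant analyte
  column, an unknown diagnosis label, and a rank-deficient design all
  raise errors naming the offending object rather than proceeding.
* Determinism: the generator derives all randomness from one seed via
  fixed sub-stream offsets; refitting PLS-DA or re-running the pipeline
  with the same configuration is bit-stable.

## Known limitations

The adaptive single-level branch cut (above) trades the published
algorithm's multi-scale resolution for robustness and determinism.
Left-censored imputation is the protocol's half-LOD / half-minimum
rule, not a truncated-likelihood estimator. The Winkler-style screen is
implemented per unit type (modules and single metabolites form separate
families). Medication residuals are not re-standardized. The
Mahalanobis screen requires $n > p$ and is applied to the full analyte
matrix, which is the stricter reading of the protocol.
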