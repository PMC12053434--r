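---
title: "Methods: epi-score modeling of targeted methylation cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epi-score modeling of targeted methylation cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcore)
```

# The model

The package is built around one linear model of a methylation cohort. For
sample $i$, CpG site $j$ and trait $k$,

$$M_{ij} = \sum_k T_{ik}\, C_{kj},$$

where $M$ is the samples $\times$ sites matrix of methylation fractions,
$T$ the samples $\times$ traits design (age in years, binary traits coded
0/1, cell-composition and ancestry covariates as continuous columns) and
$C$ the traits $\times$ sites coefficient matrix describing how each site
responds to each trait. Both estimation steps are Moore–Penrose
pseudoinverses:

* **Fitting** (`fit_mmlr()`): $C = T^{+} M$ — simultaneously the
  minimum-norm least-squares solution of every per-site regression.
* **Prediction** (`predict_traits()`): $\hat T = M_{\text{new}}\, C^{+}$ —
  the model is inverted, so a frozen coefficient matrix scores any sample
  whose sites align, whether or not it was in the training cohort.

The predicted value $\hat T_{ik}$ is the sample's *epi score* for trait
$k$: epi-ATG for the immunosuppressant exposure, epi-infection for
infection risk, EpiAge for age. `loocv_episcores()` produces one epi score
per sample from a model trained without that sample (leave-one-out), which
is what every downstream evaluation uses. In paired designs the
recommended `group_by_subject = TRUE` holds both of a subject's samples
out together; a subject's pre- and post-transplant samples share trait
information, and splitting them across folds leaks it.

Three deliberate conventions, each exposed as a flag:

* **No implicit intercept.** The model above has none; an explicit column
  of ones can be requested in `encode_traits()`. Silent augmentation would
  change the dimensions of $C$.
* **Traits enter unstandardized** by default; `standardize = TRUE`
  z-scores continuous columns and records the scaling inside the fit so
  predictions decode back to original units.
* **Pseudoinverse tolerance.** Singular values below
  $\max(\mathrm{dim}) \cdot \varepsilon \cdot \sigma_{\max}$ are treated
  as zero — the standard SVD cutoff, so rank-deficient designs
  (duplicated traits, constant columns) return the minimum-norm solution
  rather than failing.

Binary epi scores are left continuous; evaluation is by tie-aware AUC
(`roc_auc()`, the normalized Mann–Whitney statistic computed from
midranks) and rank-sum group tests, matching how such predictors are
reported. A Youden-threshold helper exists for users who need hard calls.
The baseline comparator, `fit_penalized_logistic()`, is an L2-penalized
logistic regression on the sites themselves (Newton/IRLS to gradient
tolerance $10^{-6}$, intercept unpenalized, deterministic stratified
folds); L2 was chosen because it keeps the objective strictly convex with
a closed Newton step whatever the site count.

# Cell-type deconvolution

Blood methylation is a mixture signal, so cell composition must be both
estimated (it is biology of interest) and controlled for (it confounds
trait associations). The reference-based route has two halves:

1. **Marker discovery** (`call_celltype_dmrs()`): one-vs-all comparisons
   on a replicated reference panel. Per cell type, the per-site delta is
   its replicate mean minus the pooled mean of all other replicates;
   candidate regions are maximal runs of consecutive sites with delta at
   or below the threshold (default $-0.30$, i.e. 30 percentage points
   below the rest), broken where neighbouring CpGs are more than the gap
   window apart (default 300 bp); regions must span at least 500 bp; each
   is tested by a rank-sum test of region-mean methylation between the
   cell type's replicates and the rest, with Benjamini–Hochberg control at
   FDR 0.05 across all candidates. Only hypomethylated markers are used —
   the selection contract is stated for hypomethylation. The run-based
   caller, the gap window and the rank-sum region test are this package's
   own documented choices; region span is measured as last minus first
   CpG position.
2. **Fraction estimation** (`estimate_cell_fractions()`): nonnegative
   least squares (Lawson–Hanson) of each sample against the cell-type
   mean profiles restricted to the marker sites. Raw NNLS coefficients
   need not sum to one; they are renormalized by default so they read as
   mixture fractions, with the raw sum retained — both behaviours are
   available because neither is canonical.

`compute_cell_pcs()` turns the fraction matrix into centred principal
components for use as covariates. With $c$ cell types the fractions live
on a $(c-1)$-simplex, so $c-1$ PCs (the pipeline default) capture the
mixture exactly; the leading loading of each component is forced positive
so scores are reproducible across BLAS implementations.

# Site-wise association

`fit_sitewise_models()` regresses every site's methylation fraction on
the explanatory variables (trait of interest plus age, sex, CMV
serostatus, transplant state, infection risk, cell-type PCs, ancestry
PCs) with an intercept, by ordinary least squares. All sites share one
design, so one QR decomposition serves the whole matrix; coefficients,
standard errors and two-sided t-tests are exact OLS results, not
approximations. P-values are BH-adjusted *per explanatory variable across
sites* — the closest reading of adjusting "per explanatory variable" —
and `select_trait_associated_sites()` applies the adjusted-p cutoff plus
an optional sign filter (the hyper-methylated set is
`direction = "positive"`: two-sided tests, then sign selection).
Methylation is modeled on the fraction scale; no logit transform is
applied because a linear additive effect on the fraction scale is the
generating model of the synthetic data, and the field's delta thresholds
are conventionally stated on that scale.

`methylation_expression_correlation()` implements the downstream filter:
Pearson correlation of mapped site–gene pairs across shared samples,
keeping $|R| > 0.3$ and $p < 0.05$, with the sign annotated (negative =
candidate down-regulation under hyper-methylation).

# Outcomes

`build_survival_table()` collapses a cohort to one record per subject —
by default the pre-transplant sample's epi scores represent the subject,
because those are available before outcomes accrue — and restricts to
CMV-seropositive subjects, the subset in which infection follow-up is
informative. `fit_cox()` maximizes the Cox partial likelihood with the
**Efron** tie correction: follow-up is recorded in whole days, so tied
event days are guaranteed, and Efron is the lower-bias standard. The
epi-infection score enters continuously; the Kaplan–Meier median split in
`plot_km_by_score()` is display only. Covariate SDs are stored on the
fit so hazard ratios can be restated per SD when the score's scale is
arbitrary.

`moderation_analysis()` asks whether a binary factor steepens the slope
of predicted age on chronological age:
$\mathrm{EpiAge} = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,m +
\beta_3\,\mathrm{age}\times m + \varepsilon$. The interaction $\beta_3$
is the acceleration; per-group slopes are $\beta_1$ and
$\beta_1 + \beta_3$, identically equal to separate within-group
regressions.

# The synthetic cohort generator

Every recovery test runs against cohorts with exact ground truth, built
by `sim_config()` + `simulate_reference_panel()` + `simulate_cohort()` +
`simulate_survival()` (+ `simulate_expression()`). What it emulates, and
the defaults chosen as the study conditions:

* **Reference panel:** six immune cell types, three replicates each, on a
  synthetic chromosome of 8,000 CpGs spaced 50 bp apart. Baselines are
  bimodal (beta modes near 0.05 and 0.95, shared across types up to small
  jitter), like real CpG methylomes. Five hypomethylated marker blocks
  per type span 600 bp with the marked type exactly 0.40 below the others
  (fixed at 0.90 there), so marker truth is unambiguous. Replicates add
  beta noise (concentration 150, i.e. SD ≈ 0.02–0.04).
* **Cohort:** 90 subjects by default, paired pre/post samples; cell
  fractions per sample from a Dirichlet with a CD4-dominant PBMC-like
  concentration (6, 4, 3, 2, 2, 1); sample profile = fraction-weighted
  average of the reference methylomes (a convex combination), plus
  Gaussian noise (SD 0.05) and clipping to [0, 1].
* **Traits and effects:** age uniform on 25–70 y; sex, CMV and the
  induction arm Bernoulli (0.6, 0.6, 0.5). Additive effects at disjoint
  recorded site sets: +0.15 at 100 sites for ATG exposure, +0.10 at 100
  sites each for transplant state and infection risk, ±0.002/yr at 200
  sites for age. Effect sites are drawn only where the shifted mean stays
  inside [0.02, 0.95] — an effect planted against the boundary would be
  clipped away, which is also why real hyper-methylation responses occur
  at sites with headroom. ATG exposure is a *sample-level* property: the
  post-transplant sample of an induced subject. The transplant effect
  lives on a separate site set so the two are separable by construction
  (in the real design they are confounded).
* **Outcomes:** a latent infection propensity (weighted scaled age + CMV
  + induction arm + unit noise, thresholded at the 70th percentile to
  label risk) drives an exponential (or Weibull) hazard with log hazard
  ratio $\ln 3$ per SD, day-resolution times, administrative censoring at
  day 365, baseline rate 0.002/day (≈ 50% event probability in the
  window).

One root seed expands into fixed per-generator streams, so regenerating
one component never shifts another — stable regression tests. Every
generator is a pure function of its configuration.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: read-depth/beta-binomial noise
(the target matrix is already coverage-filtered, so Gaussian-and-clip is
used), genomic autocorrelation beyond the planted blocks, batch and
array effects, within-subject correlation of repeated Dirichlet draws,
cell-type profiles estimated with error, and the confounding structure
of a real transplant cohort (here transplant and induction effects are
separable by design).

# Problem sizes and numerical choices

The test suite and the acceptance script size their simulations as
follows: exactness checks on a 40 samples × 6 traits × 500 sites
noiseless construction plus 100 random small instances against
normal-equation/SVD oracles; epi-score recovery on one 100-sample,
8,000-site cohort with 20 label permutations; deconvolution on 100
Dirichlet mixtures (noise SD 0.02) plus 20 null panels; association
recovery over 20 simulated cohorts with 2,000 pure-noise sites for the
uniformity check; hazard recovery over 50 cohorts of 200 subjects;
moderation over 100 samples with a 50-replicate null. These sizes give
stable Monte-Carlo summaries (binomial SE of a coverage estimate at 50
replicates is ≈ 0.03) while a full run stays comfortably interactive.

Degenerate inputs are contracts, not surprises: constant binary traits
in a training fold warn and still predict; duplicated reference profiles
warn about arbitrary fraction splits; an all-zero NNLS solution under
renormalization is an error; complete separation in the Cox model is an
error rather than a silently divergent coefficient; constant vectors in
correlation matrices come back as `NA` with a warning.

# Limitations

The epi-score model is linear in traits and sites; it neither selects
sites nor regularizes, so its coefficients are not sparse biomarker
panels. LOOCV under label permutation shows the usual slight
anti-learning bias (null AUC mildly below 0.5), which is why the null
band is stated symmetrically around 0.5 rather than as a point. Hazard
ratios for an epi score depend on the score's scale, which the model
does not fix — hence the stored covariate SDs. The DMR caller is a
transparent run-based selector honoring the stated length/delta/FDR
contract; it is not a reimplementation of segmentation tools and will
differ from them away from clear-cut blocks.
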