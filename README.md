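# episcore

Modeling toolkit for targeted bisulfite sequencing (TBS-seq) cohorts:
predict clinical traits from DNA methylation, decompose blood methylomes
into immune cell-type fractions, find trait-associated CpG sites, and
link methylation-derived scores to time-to-event outcomes. The intended
user is an epigenomics analyst holding a CpG × sample methylation-fraction
matrix and a clinical metadata table — for example from a kidney-transplant
cohort sampled before and after transplantation — who wants the full path
from matrix to interpretable numbers, plus a ground-truthed synthetic
cohort generator to validate every step.

## The model

The core is a multivariate multiple linear regression (MMLR) solved by
pseudoinverse. With $M$ the samples × sites methylation matrix and $T$
the samples × traits design (age, sex, CMV serostatus, ATG induction,
transplant state, infection risk, cell-type PCs, ancestry PCs):

$$M = T\,C, \qquad C = T^{+} M, \qquad \hat T = M_{\text{new}}\,C^{+}$$

The coefficient matrix $C$ is estimated with the Moore–Penrose
pseudoinverse of $T$; inverting the model with $C^{+}$ predicts traits
for any sample from its methylation alone. The leave-one-out predicted
value of a trait is that sample's **epi score** (epi-ATG, epi-infection,
EpiAge, ...). Around this sit:

- **Reference-based deconvolution** — one-vs-all hypomethylated marker
  regions (≥ 500 bp, delta < −30%, FDR < 0.05) from a replicated
  cell-type panel, then nonnegative least squares for per-sample
  fractions (`call_celltype_dmrs()`, `estimate_cell_fractions()`).
- **Site-wise association** — per-CpG OLS with covariate adjustment and
  per-variable Benjamini–Hochberg correction; trait-associated sites are
  those with adjusted p < 0.05, optionally sign-filtered
  (`fit_sitewise_models()`, `select_trait_associated_sites()`).
- **Outcomes** — Cox proportional hazards (Efron ties) of time to
  infection on the epi-infection score in CMV-seropositive subjects, and
  moderation analysis of EpiAge (age × factor interaction) for
  epigenetic-age acceleration (`fit_cox()`, `moderation_analysis()`).
- **Synthetic cohorts** — Dirichlet cell mixtures over a simulated
  reference panel, additive trait effects at recorded sites, exponential
  or Weibull survival driven by a latent infection propensity
  (`sim_config()`, `simulate_cohort()`, `simulate_survival()`).

Results come back as tibbles; fitted objects have `tidy()`, `glance()`
and `autoplot()`/`plot_*()` methods.

## Worked example

```r
library(episcore)

cfg     <- sim_config(n_subjects = 40, n_sites = 4000, seed = 42)
panel   <- simulate_reference_panel(cfg)
cohort  <- simulate_survival(simulate_cohort(cfg, panel))

markers <- call_celltype_dmrs(panel)
markers
#> <marker_set> 30 regions over 6 cell types (390 marker sites)

fractions <- estimate_cell_fractions(cohort$methylation, panel, markers)
head(fractions, 3)
#> # A tibble: 3 × 8
#>   sample_id     B  CD4T  CD8T     NK naiveT   Mono raw_sum
#>   <chr>     <dbl> <dbl> <dbl>  <dbl>  <dbl>  <dbl>   <dbl>
#> 1 S001_pre  0.288 0.323 0.101 0.214  0.0472 0.0271   0.997
#> 2 S001_post 0.340 0.145 0.147 0.126  0.0568 0.185    0.999
#> 3 S002_pre  0.281 0.241 0.179 0.0466 0.0493 0.203    1.00

cell_pcs <- compute_cell_pcs(fractions, 5)
traits   <- encode_traits(cohort$metadata, cell_pcs = cell_pcs)
scores   <- loocv_episcores(traits, cohort$methylation,
                            group_by_subject = TRUE,
                            subjects = cohort$metadata$subject_id)
dplyr::filter(scores$evaluation, trait %in% c("age", "atg", "infection_risk"))
#> # A tibble: 3 × 3
#>   trait          metric   value
#>   <chr>          <chr>    <dbl>
#> 1 age            spearman 0.804
#> 2 atg            auc      1
#> 3 infection_risk auc      1

fit <- fit_sitewise_models(cohort$methylation, traits)
sel <- select_trait_associated_sites(fit, "atg", direction = "positive")
nrow(sel)   # 100 hyper-methylated sites were planted
#> [1] 101

records <- build_survival_table(cohort$metadata, scores)
fit_cox(records, "epi_infection")
#> <epi_coxfit> 21 subjects, 11 events
#> # A tibble: 1 × 6
#>   term          log_hazard hazard_ratio conf_low conf_high  p_value
#>   <chr>              <dbl>        <dbl>    <dbl>     <dbl>    <dbl>
#> 1 epi_infection       3.82         45.7     5.13      407. 0.000616
```

Reading the output: the marker caller recovered all 30 planted
hypomethylated blocks; NNLS fractions track the Dirichlet mixing truth;
leave-one-out epi scores separate the injected ATG exposure and
infection-risk effects perfectly at this effect size and rank-correlate
0.80 with age; the association scan returns 101 hyper-methylated sites
against 100 planted; and the epi-infection score is a significant Cox
covariate in the CMV-positive subset (hazard ratio per unit score, wide
CI at 21 subjects).

A one-command version of the whole analysis:

```r
config <- make_demo(seed = 1, out_dir = "demo")   # flat-file synthetic bundle
run_pipeline(config)                              # deconvolve → mmlr → associate → survive → moderate
```

which writes every stage artifact (TSV/BED), a `summary.json` of the
headline numbers and a `manifest.json` with parameters and md5 sums. A
thin CLI wrapper lives at `inst/cli/episcore.R`.

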