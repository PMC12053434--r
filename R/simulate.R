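#' Simulation configuration for synthetic TBS-seq-like cohorts
#'
#' Bundles every knob of the synthetic generators with validated defaults
#' chosen to echo a paired kidney-transplant methylation cohort: 90 subjects
#' sampled pre- and post-transplant, 8,000 CpG sites on one synthetic
#' chromosome, six reference immune cell types mixed per sample from a
#' Dirichlet distribution, additive per-trait methylation effects, and
#' exponential time-to-infection outcomes over a 365-day window.
#'
#' A single `seed` expands into independent per-generator streams through a
#' fixed offset table, so regenerating one component never perturbs another.
#'
#' @param n_subjects number of subjects.
#' @param paired if `TRUE`, each subject contributes a pre- and a
#'   post-transplant sample; if `FALSE` one sample each, with transplant
#'   state and ATG exposure assigned independently per sample.
#' @param n_sites number of CpG sites.
#' @param site_spacing_bp distance between consecutive synthetic CpGs.
#' @param n_celltypes,celltype_names reference cell types (>= 2).
#' @param replicates_per_celltype WGBS-like replicates per cell type (>= 2).
#' @param dmr_blocks_per_celltype planted hypomethylated marker blocks.
#' @param dmr_block_length_bp genomic span of each planted block.
#' @param dmr_delta planted methylation difference (fraction scale, < 0):
#'   the marked cell type sits this far below every other type.
#' @param replicate_concentration beta concentration of replicate noise
#'   around the cell-type mean (larger = tighter replicates).
#' @param trait_effects named list; each element
#'   `list(n_sites =, effect =)` gives the count of affected CpGs and the
#'   additive methylation-fraction shift (per year for `age`). Site sets
#'   are disjoint and never overlap marker blocks.
#' @param noise_sd per-entry Gaussian noise on methylation fractions
#'   (clipped to \[0, 1\]).
#' @param dirichlet_alpha Dirichlet concentration of cell-type mixing.
#' @param age_range uniform age range in years.
#' @param prevalence named probabilities: `sex_m`, `cmv`, `atg`
#'   (the subject-level induction arm).
#' @param propensity_weights contribution of scaled age, CMV positivity and
#'   the induction arm to the latent infection propensity (unit Gaussian
#'   noise is always added).
#' @param infection_quantile subjects above this propensity quantile are
#'   labelled at risk of infection.
#' @param n_ancestry_pcs number of simulated ancestry covariates.
#' @param survival_model `"exponential"` or `"weibull"`.
#' @param baseline_rate baseline daily hazard of infection (> 0).
#' @param weibull_shape shape parameter when `survival_model = "weibull"`.
#' @param log_hazard log hazard ratio per SD of latent infection propensity.
#' @param censor_day administrative censoring day.
#' @param seed root seed (integer).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 90,
                       paired = TRUE,
                       n_sites = 8000,
                       site_spacing_bp = 50,
                       n_celltypes = 6,
                       celltype_names = c("B", "CD4T", "CD8T", "NK", "naiveT", "Mono", "Neu")[seq_len(n_celltypes)],
                       replicates_per_celltype = 3,
                       dmr_blocks_per_celltype = 5,
                       dmr_block_length_bp = 600,
                       dmr_delta = -0.40,
                       replicate_concentration = 150,
                       trait_effects = list(
                         atg = list(n_sites = 100, effect = 0.15),
                         transplant = list(n_sites = 100, effect = 0.10),
                         infection_risk = list(n_sites = 100, effect = 0.10),
                         age = list(n_sites = 200, effect = 0.002)
                       ),
                       noise_sd = 0.05,
                       dirichlet_alpha = c(6, 4, 3, 2, 2, 1, 1)[seq_len(n_celltypes)],
                       age_range = c(25, 70),
                       prevalence = c(sex_m = 0.6, cmv = 0.6, atg = 0.5),
                       propensity_weights = c(age = 0.5, cmv = 0.5, atg = 0.5),
                       infection_quantile = 0.7,
                       n_ancestry_pcs = 2,
                       survival_model = c("exponential", "weibull"),
                       baseline_rate = 0.002,
                       weibull_shape = 1.5,
                       log_hazard = log(3),
                       censor_day = 365,
                       seed = 1) {
  survival_model <- match.arg(survival_model)
  cfg <- list(
    n_subjects = as.integer(n_subjects), paired = isTRUE(paired),
    n_sites = as.integer(n_sites), site_spacing_bp = as.integer(site_spacing_bp),
    n_celltypes = as.integer(n_celltypes), celltype_names = celltype_names,
    replicates_per_celltype = as.integer(replicates_per_celltype),
    dmr_blocks_per_celltype = as.integer(dmr_blocks_per_celltype),
    dmr_block_length_bp = as.integer(dmr_block_length_bp),
    dmr_delta = dmr_delta,
    replicate_concentration = replicate_concentration,
    trait_effects = trait_effects, noise_sd = noise_sd,
    dirichlet_alpha = dirichlet_alpha, age_range = age_range,
    prevalence = prevalence, propensity_weights = propensity_weights,
    infection_quantile = infection_quantile,
    n_ancestry_pcs = as.integer(n_ancestry_pcs),
    survival_model = survival_model, baseline_rate = baseline_rate,
    weibull_shape = weibull_shape, log_hazard = log_hazard,
    censor_day = as.integer(censor_day), seed = as.integer(seed)
  )
  with(cfg, {
    if (n_subjects < 1 || n_sites < 1) abort("counts must be positive")
    if (n_celltypes < 2) abort("need at least 2 cell types")
    if (replicates_per_celltype < 2) {
      abort("need at least 2 replicates per cell type (the DMR test compares replicates)")
    }
    if (noise_sd < 0) abort("noise_sd must be nonnegative")
    if (dmr_delta >= 0) abort("dmr_delta must be negative (hypomethylated markers)")
    if (length(dirichlet_alpha) != n_celltypes || any(dirichlet_alpha <= 0)) {
      abort("dirichlet_alpha must be positive with one entry per cell type")
    }
    if (length(celltype_names) != n_celltypes) {
      abort("celltype_names must have one entry per cell type")
    }
    ok_eff <- vapply(trait_effects, function(e) abs(e$effect) <= 1 && e$n_sites >= 0, TRUE)
    if (!all(ok_eff)) abort("trait effects must keep fractions clippable to [0, 1]")
  })
  class(cfg) <- "sim_config"
  cfg
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a cell-type reference panel with planted marker regions
#'
#' Each cell type gets a bimodal baseline methylome (fractions concentrated
#' near 0.05 and 0.95, shared across types up to small jitter) plus
#' designated hypomethylated marker blocks where its mean sits exactly
#' `dmr_delta` below every other type (others fixed at 0.90 there, so the
#' one-vs-all contrast is unambiguous before noise). Replicates are drawn
#' from a beta distribution around each type's mean.
#'
#' @param config a [sim_config()].
#' @return a `reference_panel`: cell-type mean profiles, replicate
#'   profiles, site coordinates and the planted true marker regions
#'   (a [region_set()]).
#' @export
simulate_reference_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "panel"))
  n_sites <- config$n_sites
  spacing <- config$site_spacing_bp
  pos <- as.integer((seq_len(n_sites) - 1L) * spacing + 1L)
  sites <- make_site_ids("chrS", pos)
  ct <- config$celltype_names
  n_ct <- config$n_celltypes

  n_blocks <- n_ct * config$dmr_blocks_per_celltype
  block_len_sites <- config$dmr_block_length_bp %/% spacing + 1L
  stride <- n_sites %/% (n_blocks + 1L)
  if (n_blocks > 0 && block_len_sites > stride) {
    abort("configured marker blocks do not fit in n_sites without overlap")
  }
  block_start <- stride * seq_len(n_blocks)
  block_ct <- rep_len(seq_len(n_ct), max(n_blocks, 1L))[seq_len(n_blocks)]

  hi <- rbinom(n_sites, 1, 0.5) == 1
  consensus <- ifelse(hi, rbeta(n_sites, 38, 2), rbeta(n_sites, 2, 38))
  profiles <- matrix(rep(consensus, each = n_ct), nrow = n_ct,
    dimnames = list(ct, sites))
  profiles <- clip01(profiles + matrix(rnorm(n_ct * n_sites, 0, 0.02), nrow = n_ct))

  marker_idx <- integer(0)
  regions <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- block_start[b]:(block_start[b] + block_len_sites - 1L)
    marker_idx <- c(marker_idx, idx)
    profiles[, idx] <- 0.90
    profiles[block_ct[b], idx] <- 0.90 + config$dmr_delta
    regions[[b]] <- tibble::tibble(
      chrom = "chrS", start = pos[idx[1]] - 1L, end = pos[idx[block_len_sites]],
      label = ct[block_ct[b]], score = config$dmr_delta
    )
  }
  true_dmrs <- if (n_blocks > 0) {
    d <- dplyr::bind_rows(regions)
    region_set(d$chrom, d$start, d$end, d$label, d$score)
  } else {
    region_set()
  }

  n_rep <- config$replicates_per_celltype
  rep_ct <- rep(ct, each = n_rep)
  mu <- profiles[rep_ct, , drop = FALSE]
  mu <- pmin(pmax(mu, 0.005), 0.995)
  kappa <- config$replicate_concentration
  reps <- matrix(
    rbeta(length(mu), shape1 = as.vector(mu) * kappa, shape2 = (1 - as.vector(mu)) * kappa),
    nrow = nrow(mu), dimnames = list(paste0(rep_ct, ".rep", rep(seq_len(n_rep), times = n_ct)), sites)
  )

  structure(list(
    celltypes = ct, site_ids = sites, positions = pos,
    profiles = profiles, replicates = reps, replicate_celltype = rep_ct,
    true_dmrs = true_dmrs, marker_site_idx = sort(unique(marker_idx)),
    config = config
  ), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf(
    "<reference_panel> %d cell types x %d sites, %d replicates each, %d planted marker regions\n",
    length(x$celltypes), length(x$site_ids),
    length(x$replicate_celltype) / length(x$celltypes), nrow(x$true_dmrs)
  ))
  invisible(x)
}

#' Simulate a mixed-cell-type methylation cohort with ground truth
#'
#' Per sample: cell fractions are drawn from `Dirichlet(alpha)` and the
#' baseline profile is the fraction-weighted average of the reference
#' cell-type methylomes (a convex combination). Subject traits are then
#' assigned (uniform age, Bernoulli sex/CMV/induction arm), trait effects
#' are added at disjoint, recorded CpG sets — the ATG shift lands on
#' exposed samples (post-transplant samples of induced subjects in the
#' paired design), the transplant shift on post samples, the infection
#' shift on at-risk subjects' samples, and the age slope scales with
#' centred age — Gaussian noise is added, and values are clipped to
#' \[0, 1\]. The latent infection propensity is a linear score over scaled
#' age, CMV and induction arm plus unit noise, thresholded at
#' `infection_quantile` to label `infection_risk`.
#'
#' @param config a [sim_config()].
#' @param panel a [simulate_reference_panel()] result (defaults to
#'   simulating one from `config`).
#' @return an `epi_cohort`: `$methylation` ([methyl_matrix()]),
#'   `$metadata` (tibble), `$truth` (cell fractions, effect sites,
#'   generating coefficients, latent propensity), `$config`.
#' @export
simulate_cohort <- function(config = sim_config(), panel = simulate_reference_panel(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "reference_panel"))
  set.seed(derive_seed(config$seed, "cohort"))
  n_sub <- config$n_subjects
  subjects <- sprintf("S%03d", seq_len(n_sub))

  age <- runif(n_sub, config$age_range[1], config$age_range[2])
  sex <- ifelse(runif(n_sub) < config$prevalence[["sex_m"]], "M", "F")
  cmv <- ifelse(runif(n_sub) < config$prevalence[["cmv"]], "positive", "negative")
  arm <- runif(n_sub) < config$prevalence[["atg"]]
  ancestry <- matrix(rnorm(n_sub * config$n_ancestry_pcs), nrow = n_sub)

  w <- config$propensity_weights
  propensity_raw <- w[["age"]] * as.numeric(scale(age)) +
    w[["cmv"]] * (cmv == "positive") + w[["atg"]] * arm + rnorm(n_sub)
  at_risk <- propensity_raw > quantile(propensity_raw, config$infection_quantile)

  if (config$paired) {
    meta <- tibble::tibble(
      subject_id = rep(subjects, each = 2),
      sample_id = paste0(rep(subjects, each = 2), "_", rep(c("pre", "post"), n_sub)),
      age = rep(age, each = 2),
      sex = rep(sex, each = 2),
      cmv = rep(cmv, each = 2),
      transplant = rep(c("pre", "post"), n_sub),
      induction_arm = rep(ifelse(arm, "yes", "no"), each = 2)
    )
    meta$atg <- ifelse(meta$transplant == "post" & meta$induction_arm == "yes", "yes", "no")
  } else {
    meta <- tibble::tibble(
      subject_id = subjects,
      sample_id = paste0(subjects, "_s1"),
      age = age, sex = sex, cmv = cmv,
      transplant = ifelse(runif(n_sub) < 0.5, "post", "pre"),
      induction_arm = ifelse(arm, "yes", "no"),
      atg = ifelse(arm, "yes", "no")
    )
  }
  meta$infection_risk <- rep(ifelse(at_risk, "yes", "no"),
    each = if (config$paired) 2L else 1L)
  for (k in seq_len(config$n_ancestry_pcs)) {
    meta[[paste0("ancestry_pc", k)]] <- rep(ancestry[, k],
      each = if (config$paired) 2L else 1L)
  }
  meta$days_to_infection <- NA_real_
  meta$event_observed <- NA

  n_samp <- nrow(meta)
  fractions <- .rdirichlet(n_samp, config$dirichlet_alpha)
  dimnames(fractions) <- list(meta$sample_id, panel$celltypes)
  base <- fractions %*% panel$profiles # sample x site

  # disjoint effect-site sets: never inside marker blocks, and only where
  # the additive shift keeps the expected fraction inside [0.05, 0.95]
  # (an effect planted against the boundary would be clipped away)
  mu <- colMeans(panel$profiles)
  free <- setdiff(seq_len(config$n_sites), panel$marker_site_idx)
  effect_sites <- list()
  traits <- names(config$trait_effects)
  true_coef <- matrix(0, nrow = length(traits), ncol = config$n_sites,
    dimnames = list(traits, panel$site_ids))
  for (tr in traits) {
    spec <- config$trait_effects[[tr]]
    if (spec$n_sites == 0) {
      effect_sites[[tr]] <- tibble::tibble(site = character(), effect = numeric())
      next
    }
    hi <- if (tr == "age") abs(spec$effect) * diff(config$age_range) / 2 else max(spec$effect, 0)
    lo <- if (tr == "age") -hi else min(spec$effect, 0)
    eligible <- free[mu[free] + hi <= 0.95 & mu[free] + lo >= 0.02]
    if (spec$n_sites > length(eligible)) abort("not enough free sites for trait effects")
    idx <- sort(sample(eligible, spec$n_sites))
    free <- setdiff(free, idx)
    effect_sites[[tr]] <- tibble::tibble(site = panel$site_ids[idx], effect = spec$effect)
    true_coef[tr, idx] <- spec$effect
    carrier <- switch(tr,
      atg = meta$atg == "yes",
      transplant = meta$transplant == "post",
      infection_risk = meta$infection_risk == "yes",
      age = NULL,
      abort(paste0("no effect rule for trait '", tr, "'"))
    )
    if (tr == "age") {
      base[, idx] <- base[, idx] + spec$effect * (meta$age - mean(config$age_range))
    } else {
      base[carrier, idx] <- base[carrier, idx] + spec$effect
    }
  }

  if (config$noise_sd > 0) {
    base <- base + matrix(rnorm(length(base), 0, config$noise_sd), nrow = n_samp)
  }
  m <- methyl_matrix(t(clip01(base)), site_ids = panel$site_ids,
    sample_ids = meta$sample_id)

  truth <- list(
    true_cell_fractions = fractions,
    true_effect_sites = effect_sites,
    true_coefficients = true_coef,
    latent_infection_propensity = setNames(as.numeric(scale(propensity_raw)), subjects),
    true_log_hazard = config$log_hazard
  )
  structure(list(methylation = m, metadata = meta, truth = truth, config = config,
    panel = panel), class = "epi_cohort")
}

#' @export
print.epi_cohort <- function(x, ...) {
  cat(sprintf(
    "<epi_cohort> %d samples (%d subjects%s), %d sites\n",
    nrow(x$metadata), length(unique(x$metadata$subject_id)),
    if (x$config$paired) ", paired pre/post" else "", nrow(x$methylation)
  ))
  invisible(x)
}

#' Simulate time-to-infection outcomes for a cohort
#'
#' Event times are drawn per subject from the configured survival model
#' with hazard proportional to `exp(log_hazard * z)`, `z` the standardized
#' latent infection propensity. Times are rounded up to whole days (so tied
#' event days occur, as in calendar follow-up) and administratively
#' censored at `censor_day`.
#'
#' @param cohort an `epi_cohort` from [simulate_cohort()].
#' @param config a [sim_config()]; defaults to the cohort's own.
#' @return the cohort with `days_to_infection` / `event_observed` filled in
#'   (shared by a subject's paired samples).
#' @export
simulate_survival <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "epi_cohort"))
  if (config$baseline_rate <= 0) abort("baseline_rate must be positive")
  set.seed(derive_seed(config$seed, "survival"))
  z <- cohort$truth$latent_infection_propensity
  n <- length(z)
  mult <- exp(config$log_hazard * z)
  t_raw <- switch(config$survival_model,
    exponential = rexp(n, rate = config$baseline_rate * mult),
    weibull = rweibull(n, shape = config$weibull_shape,
      scale = (1 / config$baseline_rate) * mult^(-1 / config$weibull_shape))
  )
  days <- pmax(1, ceiling(t_raw))
  event <- days <= config$censor_day
  time <- pmin(days, config$censor_day)
  idx <- match(cohort$metadata$subject_id, names(z))
  cohort$metadata$days_to_infection <- as.numeric(time[idx])
  cohort$metadata$event_observed <- event[idx]
  cohort$truth$event_time <- setNames(as.numeric(time), names(z))
  cohort
}

#' Simulate an expression matrix correlated with methylation
#'
#' For each mapped (site, gene) pair, log-scale expression is
#' `intercept - b * methylation + noise` — anticorrelated for `b > 0`, the
#' default, mirroring promoter hypermethylation silencing nearby genes.
#' Unmapped genes are pure noise around the intercept.
#'
#' @param cohort an `epi_cohort`.
#' @param mapping tibble with columns `site`, `gene`; defaults to mapping
#'   the cohort's planted ATG effect sites one-to-one onto synthetic genes.
#' @param b methylation-expression slope (positive = anticorrelated).
#' @param intercept baseline log expression.
#' @param expr_noise_sd Gaussian noise on expression.
#' @param n_null_genes additional unmapped pure-noise genes.
#' @return list with `$expression` (gene x sample matrix) and `$mapping`.
#' @export
simulate_expression <- function(cohort, mapping = NULL, b = 4, intercept = 8,
                                expr_noise_sd = 0.5, n_null_genes = 100) {
  stopifnot(inherits(cohort, "epi_cohort"))
  set.seed(derive_seed(cohort$config$seed, "expression"))
  if (is.null(mapping)) {
    sites <- cohort$truth$true_effect_sites$atg$site
    if (!length(sites)) abort("no ATG effect sites to map; supply `mapping`")
    mapping <- tibble::tibble(site = sites, gene = sprintf("G%04d", seq_along(sites)))
  }
  missing <- setdiff(mapping$site, rownames(cohort$methylation))
  if (length(missing)) abort("mapping refers to sites absent from the cohort matrix")
  m <- unclass(cohort$methylation)[mapping$site, , drop = FALSE]
  n_samp <- ncol(m)
  mapped <- intercept - b * m +
    matrix(rnorm(length(m), 0, expr_noise_sd), nrow = nrow(m))
  rownames(mapped) <- mapping$gene
  nulls <- matrix(intercept + rnorm(n_null_genes * n_samp, 0, expr_noise_sd),
    nrow = n_null_genes,
    dimnames = list(sprintf("N%04d", seq_len(n_null_genes)), colnames(m)))
  list(expression = rbind(mapped, nulls), mapping = mapping)
}

#' Simulate predicted-age data with a planted moderation effect
#'
#' Generates `epiage = intercept + slope * age + interaction * age *
#' moderator + noise`, the data-generating process probed by
#' [moderation_analysis()].
#'
#' @param n samples.
#' @param slope age slope in the moderator = 0 group.
#' @param interaction added slope in the moderator = 1 group.
#' @param moderator_prevalence probability of moderator = 1.
#' @param noise_sd residual SD in years.
#' @param age_range uniform age range.
#' @param intercept baseline predicted age offset.
#' @param seed integer seed.
#' @return tibble with `age`, `moderator` (0/1), `epiage`.
#' @export
simulate_moderation_data <- function(n = 100, slope = 1, interaction = 0.5,
                                     moderator_prevalence = 0.5, noise_sd = 2,
                                     age_range = c(25, 70), intercept = 0,
                                     seed = 1) {
  set.seed(derive_seed(seed, "moderation"))
  age <- runif(n, age_range[1], age_range[2])
  moderator <- as.integer(runif(n) < moderator_prevalence)
  epiage <- intercept + slope * age + interaction * age * moderator +
    rnorm(n, 0, noise_sd)
  tibble::tibble(age = age, moderator = moderator, epiage = epiage)
}
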