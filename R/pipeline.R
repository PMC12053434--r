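#' Pipeline configuration
#'
#' Validates and bundles everything [run_pipeline()] needs: either a
#' simulation config (synthetic mode) or paths to a methylation matrix,
#' metadata table and reference panel, plus every stage parameter. Stages
#' run in dependency order `deconvolve -> mmlr -> associate -> survive ->
#' moderate`; disabling `deconvolve` while the model requests cell-type
#' PCs is a configuration error.
#'
#' @param out_dir run directory (created if needed).
#' @param seed root seed for every stochastic stage.
#' @param sim a [sim_config()] for synthetic mode, or `NULL` to read
#'   inputs from `matrix_path` / `metadata_path` / `panel_path`.
#' @param matrix_path,metadata_path,panel_path input files (file mode).
#' @param stages character subset of
#'   `c("deconvolve", "mmlr", "associate", "survive", "moderate")`.
#' @param dmr_min_length_bp,dmr_delta,dmr_fdr,dmr_gap_bp DMR caller
#'   parameters (see [call_celltype_dmrs()]).
#' @param n_cell_pcs cell-composition PCs for the trait/covariate sets
#'   (`NULL` = one fewer than the number of cell types).
#' @param traits metadata traits entering the MMLR and association models.
#' @param group_by_subject leave paired samples out together in LOOCV.
#' @param alpha,direction trait-associated site selection parameters.
#' @param association_trait which trait's associated sites to report.
#' @param cox_covariates epi-score covariates for the Cox model.
#' @param cmv_filter restrict survival analysis to CMV-seropositive
#'   subjects.
#' @param moderators metadata factors tested as moderators of epigenetic
#'   aging.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            sim = sim_config(seed = seed),
                            matrix_path = NULL, metadata_path = NULL,
                            panel_path = NULL,
                            stages = c("deconvolve", "mmlr", "associate",
                                       "survive", "moderate"),
                            dmr_min_length_bp = 500, dmr_delta = -0.30,
                            dmr_fdr = 0.05, dmr_gap_bp = 300,
                            n_cell_pcs = NULL,
                            traits = c("age", "sex", "cmv", "atg",
                                       "transplant", "infection_risk"),
                            group_by_subject = TRUE,
                            alpha = 0.05, direction = "positive",
                            association_trait = "atg",
                            cox_covariates = "epi_infection",
                            cmv_filter = TRUE,
                            moderators = c("transplant", "atg")) {
  bad_stage <- setdiff(stages, c("deconvolve", "mmlr", "associate", "survive", "moderate"))
  if (length(bad_stage)) {
    abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")),
      class = "episcore_config_error")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    abort("`sim` must be a sim_config() or NULL", class = "episcore_config_error")
  }
  if (is.null(sim)) {
    for (p in c(matrix_path, metadata_path, panel_path)) {
      if (is.null(p) || !file.exists(p)) {
        abort(sprintf("input file missing: %s", p %||% "(unset)"),
          class = "episcore_config_error")
      }
    }
  }
  uses_cell_pcs <- any(c("mmlr", "associate") %in% stages)
  if (uses_cell_pcs && !"deconvolve" %in% stages) {
    abort("the model stages request cell-type PCs but 'deconvolve' is disabled",
      class = "episcore_config_error")
  }
  if (("survive" %in% stages || "moderate" %in% stages) && !"mmlr" %in% stages) {
    abort("'survive'/'moderate' need epi scores from the 'mmlr' stage",
      class = "episcore_config_error")
  }
  if (alpha < 0 || alpha > 1 || dmr_fdr <= 0 || dmr_fdr > 1) {
    abort("alpha and dmr_fdr must lie in (0, 1]", class = "episcore_config_error")
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), sim = sim,
    matrix_path = matrix_path, metadata_path = metadata_path,
    panel_path = panel_path, stages = stages,
    dmr_min_length_bp = dmr_min_length_bp, dmr_delta = dmr_delta,
    dmr_fdr = dmr_fdr, dmr_gap_bp = dmr_gap_bp, n_cell_pcs = n_cell_pcs,
    traits = traits, group_by_subject = group_by_subject,
    alpha = alpha, direction = direction,
    association_trait = association_trait,
    cox_covariates = cox_covariates, cmv_filter = cmv_filter,
    moderators = moderators
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every artifact
#' (TSV/BED flat files) plus `summary.json` (the headline numbers of each
#' stage) and `manifest.json` (parameters, seed and md5 of every artifact)
#' into the run directory. Deterministic stages are bit-identical across
#' reruns with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @return the summary (a `pipeline_run` list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  save_tsv <- function(df, name) {
    path <- file.path(out, name)
    readr::write_tsv(df, path, progress = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }
  summary <- list(seed = config$seed)

  # --- inputs -----------------------------------------------------------
  if (!is.null(config$sim)) {
    inform("[simulate] generating synthetic cohort")
    panel <- simulate_reference_panel(config$sim)
    cohort <- simulate_survival(simulate_cohort(config$sim, panel))
    m <- cohort$methylation
    meta <- cohort$metadata
    write_methylation_matrix(m, file.path(out, "methylation.tsv"))
    write_sample_metadata(meta, file.path(out, "metadata.tsv"))
    write_reference_panel(panel, file.path(out, "panel.tsv"))
    artifacts <- c(artifacts, file.path(out, c("methylation.tsv", "metadata.tsv", "panel.tsv")))
  } else {
    inform("[load] reading inputs")
    m <- read_methylation_matrix(config$matrix_path)
    meta <- read_sample_metadata(config$metadata_path)
    panel <- read_reference_panel(config$panel_path)
    cohort <- NULL
  }
  meta <- join_metadata(m, meta)
  summary$n_samples <- ncol(m)
  summary$n_sites <- nrow(m)

  cell_pcs <- NULL
  panel_scores <- NULL

  # --- deconvolve -------------------------------------------------------
  if ("deconvolve" %in% config$stages) {
    inform("[deconvolve] calling marker DMRs and estimating fractions")
    markers <- call_celltype_dmrs(panel,
      min_length_bp = config$dmr_min_length_bp,
      delta_threshold = config$dmr_delta,
      fdr = config$dmr_fdr, gap_bp = config$dmr_gap_bp)
    fractions <- estimate_cell_fractions(m, panel, markers)
    n_pcs <- config$n_cell_pcs %||% (length(panel$celltypes) - 1L)
    cell_pcs <- compute_cell_pcs(fractions, n_pcs)
    write_regions_bed(marker_regions(markers), file.path(out, "marker_regions.bed"))
    artifacts <- c(artifacts, file.path(out, "marker_regions.bed"))
    save_tsv(fractions, "cell_fractions.tsv")
    save_tsv(cell_pcs, "cell_pcs.tsv")
    summary$n_marker_regions <- nrow(markers$regions)
  }

  # --- mmlr -------------------------------------------------------------
  if ("mmlr" %in% config$stages) {
    inform("[mmlr] leave-one-out epi scores")
    traits <- encode_traits(meta, cell_pcs = cell_pcs, traits = config$traits)
    panel_scores <- loocv_episcores(traits, m,
      group_by_subject = config$group_by_subject,
      subjects = meta$subject_id)
    save_tsv(panel_scores$scores, "epi_scores.tsv")
    save_tsv(panel_scores$evaluation, "epi_score_evaluation.tsv")
    ev <- panel_scores$evaluation
    pick <- function(tr) {
      v <- ev$value[ev$trait == tr]
      if (length(v)) v else NA_real_
    }
    summary$epi_atg_auc <- pick("atg")
    summary$epi_infection_auc <- pick("infection_risk")
    summary$epiage_spearman <- pick("age")
  }

  # --- associate --------------------------------------------------------
  if ("associate" %in% config$stages) {
    inform("[associate] site-wise covariate-adjusted models")
    design <- encode_traits(meta, cell_pcs = cell_pcs, traits = config$traits)
    swfit <- fit_sitewise_models(m, design)
    selected <- select_trait_associated_sites(swfit,
      config$association_trait, alpha = config$alpha,
      direction = config$direction)
    save_tsv(tidy(swfit, terms = config$association_trait), "association_results.tsv")
    save_tsv(selected, "selected_sites.tsv")
    if (nrow(selected)) {
      coords <- parse_site_ids(selected$site)
      write_regions_bed(region_set(coords$chrom, coords$pos - 1L, coords$pos,
        selected$site, selected$estimate), file.path(out, "selected_sites.bed"))
      artifacts <- c(artifacts, file.path(out, "selected_sites.bed"))
    }
    summary$n_selected_sites <- nrow(selected)
  }

  # --- survive ----------------------------------------------------------
  if ("survive" %in% config$stages) {
    inform("[survive] Cox model on epi scores")
    records <- build_survival_table(meta, panel_scores,
      cmv_filter = config$cmv_filter)
    cox <- fit_cox(records, config$cox_covariates)
    save_tsv(records, "survival_table.tsv")
    save_tsv(cox$summary, "cox_summary.tsv")
    km <- plot_km_by_score(records, config$cox_covariates[1])
    lead <- cox$summary[cox$summary$term == config$cox_covariates[1], ]
    summary$cox_hr <- lead$hazard_ratio
    summary$cox_p <- lead$p_value
    summary$logrank_p <- km$logrank_p
    summary$n_survival_subjects <- nrow(records)
    summary$n_events <- sum(records$event)
  }

  # --- moderate ---------------------------------------------------------
  if ("moderate" %in% config$stages) {
    inform("[moderate] epigenetic-age moderation analysis")
    if (!"age" %in% config$traits) {
      abort("moderation needs the 'age' trait in the MMLR model",
        class = "episcore_config_error")
    }
    epiage <- panel_scores$scores$age
    mods <- purrr::map_dfr(config$moderators, function(f) {
      moderator <- as.numeric(meta[[f]] %in% c("yes", "post", "positive", "M"))
      fit <- moderation_analysis(epiage, meta$age, moderator)
      dplyr::mutate(glance(fit), moderator = f, .before = 1)
    })
    save_tsv(mods, "moderation_results.tsv")
    for (i in seq_len(nrow(mods))) {
      summary[[paste0("moderation_", mods$moderator[i], "_interaction")]] <-
        mods$interaction[i]
      summary[[paste0("moderation_", mods$moderator[i], "_p")]] <-
        mods$interaction_p[i]
    }
  }

  # --- summary & manifest ----------------------------------------------
  jsonlite::write_json(summary, file.path(out, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), c("out_dir", "sim"))],
    sim = if (!is.null(config$sim)) unclass(config$sim),
    artifacts = as.list(tools::md5sum(sort(c(artifacts, file.path(out, "summary.json")))))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  structure(summary, class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-32s %s\n", k, if (is.numeric(v)) signif(v, 4) else v))
  }
  invisible(x)
}

#' Write a ready-to-run synthetic demo
#'
#' Emits a complete synthetic cohort — methylation matrix, metadata with
#' survival outcomes, reference panel — plus ground-truth sidecar tables
#' and a YAML configuration, so the whole pipeline can be rerun from flat
#' files. Defaults echo the scale of a paired transplant cohort: 90
#' subjects sampled pre/post, 8,000 CpGs, six reference cell types.
#'
#' @param seed root seed.
#' @param out_dir target directory.
#' @param n_subjects,n_sites cohort dimensions.
#' @param ... further arguments to [sim_config()].
#' @return a [pipeline_config()] pointing at the emitted files, invisibly.
#' @export
make_demo <- function(seed = 1, out_dir, n_subjects = 90, n_sites = 8000, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    abort(paste0("output directory is not writable: ", out_dir))
  }
  cfg <- sim_config(seed = seed, n_subjects = n_subjects, n_sites = n_sites, ...)
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_survival(simulate_cohort(cfg, panel))
  write_methylation_matrix(cohort$methylation, file.path(out_dir, "methylation.tsv"))
  write_sample_metadata(cohort$metadata, file.path(out_dir, "metadata.tsv"))
  write_reference_panel(panel, file.path(out_dir, "panel.tsv"))
  write_regions_bed(panel$true_dmrs, file.path(out_dir, "true_marker_regions.bed"))
  truth_sites <- purrr::imap_dfr(cohort$truth$true_effect_sites, function(d, tr) {
    dplyr::mutate(d, trait = tr, .before = 1)
  })
  readr::write_tsv(truth_sites, file.path(out_dir, "true_effect_sites.tsv"),
    progress = FALSE)
  readr::write_tsv(
    tibble::as_tibble(cohort$truth$true_cell_fractions, rownames = "sample_id"),
    file.path(out_dir, "true_cell_fractions.tsv"), progress = FALSE)
  config <- pipeline_config(
    out_dir = file.path(out_dir, "run"), seed = seed, sim = NULL,
    matrix_path = file.path(out_dir, "methylation.tsv"),
    metadata_path = file.path(out_dir, "metadata.tsv"),
    panel_path = file.path(out_dir, "panel.tsv")
  )
  yaml::write_yaml(
    list(
      seed = seed,
      matrix_path = config$matrix_path,
      metadata_path = config$metadata_path,
      panel_path = config$panel_path,
      out_dir = config$out_dir
    ),
    file.path(out_dir, "config.yaml")
  )
  invisible(config)
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file as written by [make_demo()] (keys mirror
#'   [pipeline_config()] arguments).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path),
    class = "episcore_config_error")
  vals <- yaml::read_yaml(path)
  vals["sim"] <- list(NULL) # file mode: inputs come from the listed paths
  do.call(pipeline_config, vals)
}
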