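#' Build a per-subject survival table from metadata and epi scores
#'
#' Collapses paired samples to one record per subject — by default the
#' pre-transplant sample's epi scores represent the subject, since those
#' are available before outcomes accrue — and, following the study design,
#' restricts to CMV-seropositive subjects when `cmv_filter` is on. Time is
#' `days_to_infection` (the censoring time when no event was observed,
#' capped at the follow-up window).
#'
#' @param metadata metadata tibble with survival fields filled in.
#' @param panel an `episcore_panel` (or tibble of scores with
#'   `sample_id`); score columns are copied onto the records as
#'   `epi_<trait>`.
#' @param score_traits which predicted traits to carry over.
#' @param cmv_filter keep CMV-seropositive subjects only.
#' @param use_sample `"pre"` or `"post"`: which paired sample's scores
#'   represent the subject.
#' @return tibble: `subject_id`, `time`, `event`, `epi_*` covariates,
#'   `induction_arm` when present.
#' @export
build_survival_table <- function(metadata, panel,
                                 score_traits = c("infection_risk", "atg"),
                                 cmv_filter = TRUE,
                                 use_sample = c("pre", "post")) {
  use_sample <- match.arg(use_sample)
  scores <- if (inherits(panel, "episcore_panel")) panel$scores else panel
  meta <- metadata
  if (cmv_filter) meta <- meta[meta$cmv == "positive", , drop = FALSE]
  has_outcome <- !is.na(meta$event_observed)
  bad <- has_outcome & meta$event_observed & is.na(meta$days_to_infection)
  if (any(bad)) {
    abort(sprintf("subject '%s' has an observed event but no time",
      meta$subject_id[bad][1]))
  }
  meta <- meta[has_outcome & !is.na(meta$days_to_infection), , drop = FALSE]
  # representative sample per subject
  picked <- meta |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$transplant != use_sample, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  idx <- match(picked$sample_id, scores$sample_id)
  if (anyNA(idx)) {
    abort(paste0("epi scores missing for sample(s): ",
      paste(head(picked$sample_id[is.na(idx)], 3), collapse = ", ")))
  }
  out <- tibble::tibble(
    subject_id = picked$subject_id,
    time = picked$days_to_infection,
    event = picked$event_observed
  )
  if (any(out$time <= 0)) abort("survival times must be positive")
  for (tr in score_traits) {
    if (!tr %in% names(scores)) abort(paste0("trait '", tr, "' not in the epi-score panel"))
    out[[paste0("epi_", sub("_risk$", "", tr))]] <- scores[[tr]][idx]
  }
  if ("induction_arm" %in% names(picked)) {
    out$induction_arm <- as.numeric(picked$induction_arm == "yes")
  }
  out
}

#' Cox proportional hazards fit on epi-score covariates
#'
#' Maximizes the Cox partial likelihood with the Efron approximation for
#' tied event days (day-resolution follow-up guarantees ties) via
#' `survival::coxph`, reporting per-covariate log-hazards, hazard ratios
#' with 95% Wald intervals and p-values. Constant covariates are dropped
#' with a warning (their log-hazard is inestimable); each retained
#' covariate's SD is recorded so hazard ratios can be read per-SD.
#'
#' @param records survival tibble from [build_survival_table()].
#' @param covariates covariate column names to include.
#' @return an `epi_coxfit` wrapping the `coxph` fit, with `$summary`
#'   (tidy per-covariate tibble) and `$covariate_sd`.
#' @export
fit_cox <- function(records, covariates) {
  if (!all(covariates %in% names(records))) {
    abort(paste0("covariate(s) not in records: ",
      paste(setdiff(covariates, names(records)), collapse = ", ")))
  }
  if (sum(records$event) < 1) abort("no observed events; Cox model is undefined")
  keep <- vapply(covariates, function(v) {
    x <- records[[v]]
    is.finite(sd(x)) && sd(x) > 0
  }, TRUE)
  if (any(!keep)) {
    warn(paste0("dropping constant covariate(s): ",
      paste(covariates[!keep], collapse = ", ")))
    covariates <- covariates[keep]
  }
  if (!length(covariates)) abort("no usable covariates remain")
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 50)) {
    abort("Cox fit did not converge (monotone likelihood / complete separation?)")
  }
  s <- summary(fit)
  summ <- tibble::tibble(
    term = rownames(s$coefficients),
    log_hazard = s$coefficients[, "coef"],
    hazard_ratio = s$coefficients[, "exp(coef)"],
    conf_low = s$conf.int[, "lower .95"],
    conf_high = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"]
  )
  structure(list(
    fit = fit, summary = summ,
    covariate_sd = vapply(covariates, function(v) sd(records[[v]]), 0),
    n = nrow(records), n_events = sum(records$event),
    loglik = fit$loglik[length(fit$loglik)]
  ), class = "epi_coxfit")
}

#' @export
print.epi_coxfit <- function(x, ...) {
  cat(sprintf("<epi_coxfit> %d subjects, %d events\n", x$n, x$n_events))
  print(x$summary)
  invisible(x)
}

#' Kaplan-Meier curves stratified by an epi score
#'
#' Splits subjects at the median score (or a supplied threshold), computes
#' the product-limit estimate per stratum and the log-rank test p-value.
#' The split is for display only; [fit_cox()] uses the continuous score.
#'
#' @param records survival tibble from [build_survival_table()].
#' @param score covariate column to stratify on.
#' @param split `"median"` or `"threshold"`.
#' @param threshold cutoff when `split = "threshold"`.
#' @return a `km_split`: `$curves` (tibble of stratum step functions),
#'   `$logrank_p`, `$strata` sizes; plot with [autoplot()].
#' @export
plot_km_by_score <- function(records, score, split = c("median", "threshold"),
                             threshold = NULL) {
  split <- match.arg(split)
  x <- records[[score]]
  cut <- if (split == "median") median(x) else threshold
  if (is.null(cut)) abort("supply `threshold` when split = 'threshold'")
  grp <- factor(ifelse(x > cut, "high", "low"), levels = c("low", "high"))
  if (any(table(grp) == 0)) abort("empty stratum: adjust the split")
  d <- data.frame(time = records$time, event = records$event, group = grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  curves <- tibble::tibble(
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    survival = sf$surv, std_err = sf$std.err
  )
  structure(list(curves = curves, logrank_p = p,
    strata = table(grp), score = score, cut = cut), class = "km_split")
}

#' @export
print.km_split <- function(x, ...) {
  cat(sprintf("<km_split> %s split at %.3g (low n=%d, high n=%d), log-rank p = %.3g\n",
    x$score, x$cut, x$strata[["low"]], x$strata[["high"]], x$logrank_p))
  invisible(x)
}

#' Moderation analysis of epigenetic age acceleration
#'
#' OLS of predicted age on chronological age, a binary moderator and their
#' interaction: `epiage ~ age + moderator + age:moderator`. A significant
#' positive interaction means the factor steepens the aging slope —
#' accelerated epigenetic aging. Per-group slopes are the model-implied
#' `slope` and `slope + interaction`.
#'
#' @param epiage predicted (epigenetic) age per sample.
#' @param age chronological age in years.
#' @param moderator binary 0/1 factor (both levels required).
#' @return a `moderation_fit`: `$coefficients` tibble,
#'   `$interaction_p`, `$slopes` (per moderator level), `$fit`.
#' @export
moderation_analysis <- function(epiage, age, moderator) {
  moderator <- as.numeric(moderator)
  if (!all(moderator %in% c(0, 1)) || length(unique(moderator)) != 2L) {
    abort("moderator must be binary 0/1 with both levels present")
  }
  if (sd(age) == 0) abort("age is constant; the slope is undefined")
  if (length(epiage) < 6) abort("need at least 6 samples")
  d <- data.frame(epiage = epiage, age = age, moderator = moderator)
  fit <- lm(epiage ~ age * moderator, data = d)
  cf <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4]
  )
  b <- coef(fit)
  structure(list(
    coefficients = coefs,
    interaction = unname(b["age:moderator"]),
    interaction_p = cf["age:moderator", 4],
    slopes = c(moderator0 = unname(b["age"]),
      moderator1 = unname(b["age"] + b["age:moderator"])),
    fit = fit, data = d
  ), class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf(
    "<moderation_fit> slope %.3f (moderator = 0) vs %.3f (moderator = 1); interaction p = %.3g\n",
    x$slopes[["moderator0"]], x$slopes[["moderator1"]], x$interaction_p))
  invisible(x)
}
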