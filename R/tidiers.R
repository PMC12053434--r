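#' Tidy an MMLR fit into a long coefficient table
#'
#' @param x an `mmlr_fit`.
#' @param ... unused.
#' @return tibble: `trait`, `site`, `estimate`.
#' @export
tidy.mmlr_fit <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "site", values_to = "estimate")
}

#' @rdname tidy.mmlr_fit
#' @export
glance.mmlr_fit <- function(x, ...) {
  tibble::tibble(
    n_traits = nrow(x$coefficients), n_sites = ncol(x$coefficients),
    frobenius_norm = sqrt(sum(x$coefficients^2)),
    standardized = !is.null(x$scaling)
  )
}

#' Tidy an epi-score panel into long actual/predicted pairs
#'
#' @param x an `episcore_panel`.
#' @param ... unused.
#' @return tibble: `sample_id`, `trait`, `actual`, `predicted`.
#' @export
tidy.episcore_panel <- function(x, ...) {
  pred <- tidyr::pivot_longer(x$scores, -"sample_id",
    names_to = "trait", values_to = "predicted")
  act <- tibble::as_tibble(x$actual, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "trait", values_to = "actual")
  dplyr::left_join(act, pred, by = c("sample_id", "trait"))
}

#' @rdname tidy.episcore_panel
#' @export
glance.episcore_panel <- function(x, ...) {
  tidyr::pivot_wider(x$evaluation, names_from = c("trait", "metric"),
    values_from = "value", names_glue = "{trait}_{metric}") |>
    dplyr::mutate(n_samples = nrow(x$scores), .before = 1)
}

#' Tidy a site-wise association fit
#'
#' @param x a `sitewise_fit`.
#' @param terms restrict to these explanatory variables (default: all
#'   except the intercept).
#' @param ... unused.
#' @return tibble: `site`, `term`, `estimate`, `se`, `statistic`,
#'   `p_value`, `p_adj`.
#' @export
tidy.sitewise_fit <- function(x, terms = setdiff(x$terms, "intercept"), ...) {
  purrr::map_dfr(terms, function(tr) {
    tibble::tibble(
      site = x$sites, term = tr,
      estimate = x$estimate[tr, ], se = x$se[tr, ],
      statistic = x$statistic[tr, ],
      p_value = x$p_value[tr, ], p_adj = x$p_adj[tr, ]
    )
  })
}

#' Tidy a Cox epi-score fit
#'
#' @param x an `epi_coxfit`.
#' @param ... unused.
#' @return per-covariate tibble with log-hazard, hazard ratio, 95% CI and
#'   Wald p.
#' @export
tidy.epi_coxfit <- function(x, ...) x$summary

#' @rdname tidy.epi_coxfit
#' @export
glance.epi_coxfit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik)
}

#' Tidy a moderation fit
#'
#' @param x a `moderation_fit`.
#' @param ... unused.
#' @return per-term coefficient tibble.
#' @export
tidy.moderation_fit <- function(x, ...) x$coefficients

#' @rdname tidy.moderation_fit
#' @export
glance.moderation_fit <- function(x, ...) {
  tibble::tibble(
    interaction = x$interaction, interaction_p = x$interaction_p,
    slope_moderator0 = x$slopes[["moderator0"]],
    slope_moderator1 = x$slopes[["moderator1"]],
    r_squared = summary(x$fit)$r.squared
  )
}
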