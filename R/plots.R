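#' Plot an ROC curve
#'
#' @param object an `epi_roc` from [roc_auc()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.epi_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Plot per-group epi-score distributions
#'
#' Violin/jitter display of LOOCV epi scores split by the actual binary
#' trait, annotated with the rank-sum p-value.
#'
#' @param panel an `episcore_panel`.
#' @param trait binary trait name.
#' @return a ggplot.
#' @export
plot_score_distribution <- function(panel, trait) {
  if (!trait %in% colnames(panel$actual)) abort(paste0("unknown trait '", trait, "'"))
  d <- tibble::tibble(
    score = panel$scores[[trait]],
    group = factor(panel$actual[, trait])
  )
  p <- group_score_test(d$score, as.numeric(as.character(d$group)))$p_value
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$score, fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.5, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = trait, y = paste0("epi-", trait, " score"),
      subtitle = sprintf("rank-sum p = %.3g", p)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of site-wise association results
#'
#' @param fit a `sitewise_fit`.
#' @param trait explanatory variable to display.
#' @param alpha adjusted-p significance line.
#' @return a ggplot of -log10 p by genomic position, significant sites
#'   highlighted.
#' @export
plot_association_manhattan <- function(fit, trait, alpha = 0.05) {
  if (!trait %in% fit$terms) abort(paste0("unknown trait '", trait, "'"))
  d <- parse_site_ids(fit$sites)
  d$p <- fit$p_value[trait, ]
  d$significant <- fit$p_adj[trait, ] < alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "Position (bp)", y = expression(-log[10] ~ p),
      colour = paste0("adj. p < ", alpha), title = trait) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves of a score split
#'
#' @param object a `km_split` from [plot_km_by_score()].
#' @param ... unused.
#' @return a ggplot of the stratified product-limit curves.
#' @export
autoplot.km_split <- function(object, ...) {
  base <- tibble::tibble(group = names(object$strata), time = 0, survival = 1)
  d <- dplyr::bind_rows(base, object$curves[, c("group", "time", "survival")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
    colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days", y = "Infection-free probability",
      colour = paste0(object$score, " (split at ", signif(object$cut, 3), ")"),
      subtitle = sprintf("log-rank p = %.3g", object$logrank_p)) +
    ggplot2::theme_minimal()
}

#' Plot a moderation fit
#'
#' @param object a `moderation_fit`.
#' @param ... unused.
#' @return a ggplot of predicted vs chronological age with per-group
#'   regression lines.
#' @export
autoplot.moderation_fit <- function(object, ...) {
  d <- object$data
  d$moderator <- factor(d$moderator)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$epiage,
    colour = .data$moderator)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Chronological age (years)", y = "Predicted age (years)",
      subtitle = sprintf("interaction p = %.3g", object$interaction_p)) +
    ggplot2::theme_minimal()
}
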