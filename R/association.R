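#' Per-CpG multiple regression against traits with covariate adjustment
#'
#' Fits, at every CpG site, an ordinary least-squares model of the
#' methylation fraction on the explanatory variables (trait of interest
#' plus covariates: age, sex, CMV, ATG, infection risk, transplant state,
#' cell-type PCs, ancestry PCs) with an intercept, and tests each
#' coefficient with a two-sided t-test. All sites share one design matrix,
#' so a single QR decomposition serves every site; results are
#' deterministic. P-values are Benjamini-Hochberg adjusted per explanatory
#' variable across sites.
#'
#' @param m a [methyl_matrix()] (sites x samples).
#' @param design sample x variable numeric matrix (an intercept column is
#'   added unless one named `intercept` is present); typically
#'   [encode_traits()] output.
#' @return a `sitewise_fit`: per-term matrices `$estimate`, `$se`,
#'   `$statistic`, `$p_value`, `$p_adj` (terms x sites), `$sigma2`
#'   (per-site residual variance), `$df`.
#' @export
fit_sitewise_models <- function(m, design) {
  X <- unclass(design)
  if (!is.matrix(X)) abort("`design` must be a numeric matrix")
  if (nrow(X) != ncol(m)) abort("design rows must align with matrix samples")
  if (!"intercept" %in% colnames(X)) {
    X <- cbind(intercept = 1, X)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) abort("need more samples than explanatory variables + 1")
  qx <- qr(X)
  if (qx$rank < p) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    abort(paste0("design is rank deficient; collinear column(s): ",
      paste(dropped, collapse = ", ")))
  }
  Y <- t(unclass(m)) # samples x sites
  beta <- qr.coef(qx, Y) # p x sites
  res <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))[order(qx$pivot)]
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  padj <- t(apply(pval, 1, p.adjust, method = "BH"))
  dn <- list(term = colnames(X), site = rownames(m))
  dimnames(beta) <- dimnames(se) <- dimnames(tstat) <- dimnames(pval) <- dimnames(padj) <- dn
  structure(list(estimate = beta, se = se, statistic = tstat,
    p_value = pval, p_adj = padj, sigma2 = sigma2, df = df,
    terms = colnames(X), sites = rownames(m)), class = "sitewise_fit")
}

#' @export
print.sitewise_fit <- function(x, ...) {
  cat(sprintf("<sitewise_fit> %d sites x %d terms (df = %d)\n",
    length(x$sites), length(x$terms), x$df))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust`); invariant to the order of the input.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Select trait-associated CpG sites
#'
#' Sites whose BH-adjusted p-value for the named explanatory variable
#' falls below `alpha`, optionally restricted by coefficient sign (the
#' hyper-methylated set is `direction = "positive"`).
#'
#' @param fit a `sitewise_fit`.
#' @param trait explanatory-variable name.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param direction `"both"`, `"positive"` or `"negative"`.
#' @return tibble: `site`, `estimate`, `p_value`, `p_adj`, ordered by
#'   adjusted p.
#' @export
select_trait_associated_sites <- function(fit, trait, alpha = 0.05,
                                          direction = c("both", "positive", "negative")) {
  direction <- match.arg(direction)
  if (!trait %in% fit$terms) {
    abort(paste0("unknown trait '", trait, "'; available: ",
      paste(setdiff(fit$terms, "intercept"), collapse = ", ")))
  }
  est <- fit$estimate[trait, ]
  keep <- fit$p_adj[trait, ] < alpha
  keep <- keep & switch(direction,
    both = TRUE, positive = est > 0, negative = est < 0)
  out <- tibble::tibble(
    site = fit$sites[keep],
    estimate = est[keep],
    p_value = fit$p_value[trait, keep],
    p_adj = fit$p_adj[trait, keep]
  )
  dplyr::arrange(out, .data$p_adj, .data$p_value)
}

#' Methylation-expression correlation filter
#'
#' Pearson correlation between each mapped CpG site's methylation and its
#' gene's expression across shared samples, keeping pairs with
#' `|R| > r_threshold` and `p < p_threshold`. The `direction` column reads
#' the sign: negative R marks candidate down-regulation by
#' hyper-methylation, positive R up-regulation.
#'
#' @param m a [methyl_matrix()] restricted to the sites of interest (extra
#'   sites are fine; only mapped ones are tested).
#' @param expression gene x sample numeric matrix.
#' @param mapping tibble with columns `site`, `gene`.
#' @param r_threshold absolute correlation cutoff (default 0.3).
#' @param p_threshold p-value cutoff (default 0.05).
#' @return tibble: `site`, `gene`, `r`, `p_value`, `direction` for passing
#'   pairs, ordered by `|r|` descending. The unfiltered table is attached
#'   as attribute `"all_pairs"`.
#' @export
methylation_expression_correlation <- function(m, expression, mapping,
                                               r_threshold = 0.3,
                                               p_threshold = 0.05) {
  if (!all(c("site", "gene") %in% names(mapping)) || nrow(mapping) == 0) {
    abort("`mapping` must be a non-empty table with columns site, gene")
  }
  shared <- intersect(colnames(m), colnames(expression))
  if (length(shared) < 3) abort("need at least 3 shared samples")
  mm <- unclass(m)[, shared, drop = FALSE]
  ee <- expression[, shared, drop = FALSE]
  pairs <- mapping[mapping$site %in% rownames(mm) & mapping$gene %in% rownames(ee), ]
  all_pairs <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    x <- mm[pairs$site[i], ]
    y <- ee[pairs$gene[i], ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(site = pairs$site[i], gene = pairs$gene[i],
        r = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(site = pairs$site[i], gene = pairs$gene[i],
      r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- all_pairs[!is.na(all_pairs$r) &
    abs(all_pairs$r) > r_threshold & all_pairs$p_value < p_threshold, ]
  out$direction <- ifelse(out$r < 0, "down", "up")
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$r)))
  attr(out, "all_pairs") <- all_pairs
  out
}
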