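#' Encode sample traits as a numeric design matrix
#'
#' Builds the sample x trait matrix consumed by [fit_mmlr()] under a fixed,
#' documented encoding: `age` in years (unstandardized), `sex` M = 1,
#' `cmv` positive = 1, `atg` yes = 1, `transplant` post = 1,
#' `infection_risk` yes = 1; cell-type PCs and `ancestry_pc*` columns enter
#' as-is. No intercept column is added implicitly — pass
#' `intercept = TRUE` to opt in to an explicit column of ones.
#'
#' @param metadata metadata tibble (see [read_sample_metadata()]).
#' @param cell_pcs optional tibble from [compute_cell_pcs()], joined on
#'   `sample_id`.
#' @param traits which metadata traits to encode, in output order.
#' @param include_ancestry include `ancestry_pc*` columns when present.
#' @param intercept prepend an explicit column of ones.
#' @return a `trait_matrix`: numeric matrix (samples x traits, rownames =
#'   sample ids) with the encoding map attached as attribute `"encoding"`.
#' @export
encode_traits <- function(metadata, cell_pcs = NULL,
                          traits = c("age", "sex", "cmv", "atg",
                                     "transplant", "infection_risk"),
                          include_ancestry = TRUE, intercept = FALSE) {
  enc <- list(
    age = function(d) d$age,
    sex = function(d) as.numeric(d$sex == "M"),
    cmv = function(d) as.numeric(d$cmv == "positive"),
    atg = function(d) as.numeric(d$atg == "yes"),
    transplant = function(d) as.numeric(d$transplant == "post"),
    infection_risk = function(d) as.numeric(d$infection_risk == "yes")
  )
  unknown <- setdiff(traits, names(enc))
  if (length(unknown)) abort(paste0("unknown trait(s): ", paste(unknown, collapse = ", ")))
  cols <- list()
  if (intercept) cols$intercept <- rep(1, nrow(metadata))
  for (tr in traits) {
    v <- enc[[tr]](metadata)
    if (anyNA(v)) {
      abort(sprintf("missing value of '%s' for sample '%s'", tr,
        metadata$sample_id[which(is.na(v))[1]]))
    }
    cols[[tr]] <- v
  }
  if (include_ancestry) {
    for (pc in grep("^ancestry_pc", names(metadata), value = TRUE)) {
      v <- metadata[[pc]]
      if (anyNA(v)) {
        abort(sprintf("missing value of '%s' for sample '%s'", pc,
          metadata$sample_id[which(is.na(v))[1]]))
      }
      cols[[pc]] <- v
    }
  }
  if (!is.null(cell_pcs)) {
    idx <- match(metadata$sample_id, cell_pcs$sample_id)
    if (anyNA(idx)) abort("cell_pcs missing for some samples")
    for (pc in setdiff(names(cell_pcs), "sample_id")) cols[[pc]] <- cell_pcs[[pc]][idx]
  }
  tmat <- do.call(cbind, cols)
  rownames(tmat) <- metadata$sample_id
  const <- apply(tmat, 2, function(x) length(unique(x)) == 1L)
  if (intercept) const["intercept"] <- FALSE
  if (any(const)) {
    warn(paste0("constant trait column(s) (rank hazard): ",
      paste(colnames(tmat)[const], collapse = ", ")))
  }
  structure(tmat, encoding = list(
    binary = c(sex = "M", cmv = "positive", atg = "yes",
      transplant = "post", infection_risk = "yes"),
    traits = colnames(tmat)
  ), class = c("trait_matrix", class(tmat)))
}

#' Fit the multivariate multiple linear regression by pseudoinverse
#'
#' The model states that each sample's methylation profile is a
#' trait-weighted combination of per-site coefficients, `M = T C` with `M`
#' samples x sites, `T` samples x traits and `C` traits x sites. The
#' coefficients are estimated in one shot as `C = pinv(T) M` — the
#' minimum-norm least-squares solution for every site simultaneously, via
#' the SVD-based Moore-Penrose [pseudoinverse()]. No intercept is added;
#' include one explicitly in `T` if desired.
#'
#' @param traits sample x trait numeric matrix ([encode_traits()]).
#' @param m a [methyl_matrix()] (sites x samples) whose columns match the
#'   rows of `traits` one-to-one. Any numeric feature x sample matrix is
#'   accepted — the model is matrix-agnostic and runs unchanged on, say,
#'   an expression matrix.
#' @param standardize z-score continuous trait columns before fitting
#'   (binary 0/1 columns are left alone); the scaling is stored so
#'   [predict_traits()] decodes predictions back to the original units.
#' @return an `mmlr_fit`: `$coefficients` (trait x site), `$traits`,
#'   `$sites`, `$scaling`.
#' @export
fit_mmlr <- function(traits, m, standardize = FALSE) {
  tmat <- unclass(traits)
  if (!is.matrix(tmat)) abort("`traits` must be a numeric matrix")
  if (nrow(tmat) != ncol(m)) {
    abort(sprintf("dimension mismatch: %d trait rows vs %d matrix samples",
      nrow(tmat), ncol(m)))
  }
  if (!is.null(rownames(tmat)) && !is.null(colnames(m)) &&
      !identical(rownames(tmat), colnames(m))) {
    abort("trait rows and matrix columns refer to different samples")
  }
  scaling <- NULL
  if (standardize) {
    is_bin <- apply(tmat, 2, function(x) all(x %in% c(0, 1)))
    ctr <- ifelse(is_bin, 0, colMeans(tmat))
    scl <- ifelse(is_bin, 1, apply(tmat, 2, sd))
    scl[scl == 0] <- 1
    tmat <- sweep(sweep(tmat, 2, ctr), 2, scl, "/")
    scaling <- list(center = ctr, scale = scl)
  }
  coefs <- pseudoinverse(tmat) %*% t(unclass(m)) # traits x sites
  dimnames(coefs) <- list(colnames(tmat), rownames(m))
  structure(list(coefficients = coefs, traits = colnames(tmat),
    sites = rownames(m), scaling = scaling), class = "mmlr_fit")
}

#' @export
print.mmlr_fit <- function(x, ...) {
  cat(sprintf("<mmlr_fit> %d traits x %d sites%s\n",
    nrow(x$coefficients), ncol(x$coefficients),
    if (is.null(x$scaling)) "" else " (standardized traits)"))
  invisible(x)
}

#' Predict traits ("epi scores") for samples from their methylation
#'
#' Inverts the fitted model: predictions are `T_hat = M_new pinv(C)`, with
#' `pinv(C)` the Moore-Penrose pseudoinverse of the coefficient matrix.
#' The prediction is independent of whether a sample took part in
#' training, so a frozen fit scores external samples.
#'
#' @param fit an `mmlr_fit`.
#' @param m_new a [methyl_matrix()] (sites x samples) over the fit's sites.
#' @return tibble: `sample_id` plus one predicted column per trait, on the
#'   original trait scale.
#' @export
predict_traits <- function(fit, m_new) {
  stopifnot(inherits(fit, "mmlr_fit"))
  if (!identical(rownames(m_new), fit$sites)) {
    if (all(fit$sites %in% rownames(m_new))) {
      m_new <- m_new[fit$sites, , drop = FALSE]
    } else {
      abort("sites of the new matrix do not align with the fitted coefficients")
    }
  }
  pred <- t(unclass(m_new)) %*% pseudoinverse(fit$coefficients)
  colnames(pred) <- fit$traits
  if (!is.null(fit$scaling)) {
    pred <- sweep(sweep(pred, 2, fit$scaling$scale, "*"), 2, -fit$scaling$center)
  }
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(m_new)),
    tibble::as_tibble(pred))
}

#' Leave-one-out cross-validated epi scores
#'
#' For each sample (or each subject, with `group_by_subject = TRUE` in
#' paired designs — the recommended setting, since a subject's two samples
#' share trait information), a separate model is fitted on all other
#' samples and the held-out sample's traits are predicted. The resulting
#' predicted values are the epi scores (epi-ATG, epi-infection, EpiAge,
#' ...). Binary traits are evaluated by tie-aware AUC, continuous traits by
#' Spearman correlation of actual vs predicted.
#'
#' @param traits sample x trait matrix ([encode_traits()]).
#' @param m a [methyl_matrix()] aligned with `traits`.
#' @param group_by_subject leave out all samples of a subject together.
#' @param subjects subject id per sample (required when
#'   `group_by_subject = TRUE`).
#' @param standardize passed to [fit_mmlr()].
#' @return an `episcore_panel`: `$scores` (tibble of LOOCV predictions),
#'   `$actual` (the observed trait matrix), `$evaluation` (per-trait
#'   metric tibble).
#' @export
loocv_episcores <- function(traits, m, group_by_subject = FALSE,
                            subjects = NULL, standardize = FALSE) {
  tmat <- unclass(traits)
  n <- nrow(tmat)
  if (n < 3) abort("leave-one-out needs at least 3 samples")
  if (nrow(tmat) != ncol(m)) abort("traits and matrix describe different numbers of samples")
  folds <- if (group_by_subject) {
    if (is.null(subjects) || length(subjects) != n) {
      abort("`subjects` (one id per sample) is required when grouping by subject")
    }
    split(seq_len(n), subjects)
  } else {
    as.list(seq_len(n))
  }
  is_bin <- apply(tmat, 2, function(x) all(x %in% c(0, 1)))
  pred <- matrix(NA_real_, n, ncol(tmat), dimnames = dimnames(tmat))
  warned <- character(0)
  mm <- unclass(m)
  for (fold in folds) {
    keep <- setdiff(seq_len(n), fold)
    tr_sub <- tmat[keep, , drop = FALSE]
    const_bin <- is_bin & apply(tr_sub, 2, function(x) length(unique(x)) == 1L)
    warned <- union(warned, colnames(tmat)[const_bin])
    fit <- fit_mmlr(tr_sub, mm[, keep, drop = FALSE], standardize = standardize)
    p <- predict_traits(fit, mm[, fold, drop = FALSE])
    pred[fold, ] <- as.matrix(p[, -1, drop = FALSE])
  }
  if (length(warned)) {
    warn(paste0("binary trait(s) constant within some training fold: ",
      paste(warned, collapse = ", ")))
  }
  evaluation <- purrr::map_dfr(colnames(tmat), function(tr) {
    a <- tmat[, tr]
    p <- pred[, tr]
    if (is_bin[tr] && length(unique(a)) == 2L) {
      tibble::tibble(trait = tr, metric = "auc", value = roc_auc(p, a)$auc)
    } else if (sd(a) > 0 && sd(p) > 0) {
      tibble::tibble(trait = tr, metric = "spearman",
        value = cor(a, p, method = "spearman"))
    } else {
      tibble::tibble(trait = tr, metric = "spearman", value = NA_real_)
    }
  })
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(tmat)),
    tibble::as_tibble(pred))
  structure(list(scores = scores, actual = tmat, evaluation = evaluation),
    class = "episcore_panel")
}

#' @export
print.episcore_panel <- function(x, ...) {
  cat(sprintf("<episcore_panel> %d samples x %d traits (LOOCV predictions)\n",
    nrow(x$scores), ncol(x$scores) - 1L))
  print(x$evaluation)
  invisible(x)
}

#' Tie-aware ROC curve and AUC
#'
#' The AUC is the normalized Mann-Whitney U statistic computed from
#' midranks, so tied scores count one half — identical scores for all
#' samples give AUC 0.5 exactly.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return an `epi_roc`: `$auc` and `$curve` (tibble of threshold, fpr,
#'   tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  if (anyNA(scores)) abort("scores contain missing values")
  r <- rank(scores) # midranks
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(t) mean(scores[labels == 1] >= t), 0),
    fpr = vapply(c(Inf, thr), function(t) mean(scores[labels == 0] >= t), 0)
  )
  structure(list(auc = auc, curve = curve, n_pos = n1, n_neg = n0),
    class = "epi_roc")
}

#' @export
print.epi_roc <- function(x, ...) {
  cat(sprintf("<epi_roc> AUC = %.3f (%d positive / %d negative)\n",
    x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal threshold of an ROC curve
#'
#' @param roc an `epi_roc`.
#' @return the threshold maximizing `tpr - fpr` (Youden's J).
#' @export
youden_threshold <- function(roc) {
  j <- roc$curve$tpr - roc$curve$fpr
  roc$curve$threshold[which.max(j)]
}

#' Spearman correlation matrix of actual vs predicted traits
#'
#' @param traits actual sample x trait matrix.
#' @param panel an `episcore_panel` aligned with `traits`.
#' @return tibble: `actual`, `predicted`, `rho`, `p_value` for every trait
#'   pair (missing with a warning where a vector is constant).
#' @export
actual_vs_predicted_correlation <- function(traits, panel) {
  tmat <- unclass(traits)
  pmat <- as.matrix(panel$scores[, -1, drop = FALSE])
  if (nrow(tmat) != nrow(pmat)) abort("traits and panel describe different samples")
  any_const <- FALSE
  out <- purrr::map_dfr(colnames(tmat), function(a) {
    purrr::map_dfr(colnames(pmat), function(p) {
      x <- tmat[, a]
      y <- pmat[, p]
      if (sd(x) == 0 || sd(y) == 0) {
        any_const <<- TRUE
        return(tibble::tibble(actual = a, predicted = p,
          rho = NA_real_, p_value = NA_real_))
      }
      ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
      tibble::tibble(actual = a, predicted = p,
        rho = unname(ct$estimate), p_value = ct$p.value)
    })
  })
  if (any_const) warn("constant trait vector(s): correlation undefined, reported as NA")
  out
}

#' Two-group test of epi-score separation
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test of the scores between
#' label groups; exact when sample sizes permit and no ties are present,
#' otherwise the tie-corrected normal approximation.
#'
#' @param scores numeric epi scores.
#' @param labels binary 0/1 labels.
#' @return list with `statistic` (U) and `p_value`.
#' @export
group_score_test <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) != 2L) abort("both classes must be present")
  ht <- suppressWarnings(wilcox.test(scores[labels == 1], scores[labels == 0]))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
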