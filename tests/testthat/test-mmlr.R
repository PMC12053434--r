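# plain feature x sample matrix with dimnames; the MMLR is matrix-agnostic
# so algebraic tests need not restrict values to [0, 1]
mm <- function(values, sites = NULL, samples = NULL) {
  rownames(values) <- sites %||% paste0("chrS:", seq_len(nrow(values)))
  colnames(values) <- samples %||% paste0("s", seq_len(ncol(values)))
  values
}

test_that("trait encoding follows the documented map", {
  md <- toy_metadata(4)
  md$age <- c(52, 40, 61, 35)
  tmat <- encode_traits(md)
  expect_identical(colnames(tmat)[1:6],
    c("age", "sex", "cmv", "atg", "transplant", "infection_risk"))
  # sample 1: 52, M, CMV+, ATG yes, pre, infection no, ancestry pc
  expect_equal(unname(unclass(tmat)[1, ]), c(52, 1, 1, 1, 0, 0, 0.25))
  # trait selection excludes columns
  t2 <- encode_traits(md, traits = c("age", "atg"), include_ancestry = FALSE)
  expect_identical(colnames(t2), c("age", "atg"))
  # constant column warning
  md$sex <- "F"
  expect_warning(encode_traits(md), "constant trait")
  md$age[1] <- NA
  expect_error(suppressWarnings(encode_traits(md)), "missing value of 'age'")
})

test_that("identity trait matrix returns the methylation profiles as coefficients", {
  set.seed(1)
  m <- mm(matrix(runif(12), 3, 4))
  tmat <- diag(4)
  rownames(tmat) <- colnames(m)
  colnames(tmat) <- paste0("t", 1:4)
  fit <- fit_mmlr(tmat, m)
  expect_equal(unname(fit$coefficients), unname(t(unclass(m))), tolerance = 1e-12)
})

test_that("noiseless construction is recovered exactly (fit and predict)", {
  set.seed(2)
  T_true <- cbind(a = c(1, 2, 3, 4), b = c(1, 0, 1, 0))
  rownames(T_true) <- paste0("s", 1:4)
  C_true <- matrix(rnorm(12), 2, 6)
  M <- mm(t(T_true %*% C_true), samples = rownames(T_true))
  fit <- fit_mmlr(T_true, M)
  # oracle: per-site ordinary least squares via normal equations
  C_oracle <- solve(crossprod(T_true)) %*% t(T_true) %*% t(unclass(M))
  expect_equal(unname(fit$coefficients), unname(C_oracle), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), unname(C_true), tolerance = 1e-10)
  # predict inverts: C has full row rank so M pinv(C) = T
  pred <- predict_traits(fit, M)
  expect_equal(as.matrix(pred[, -1]), T_true, tolerance = 1e-8,
    ignore_attr = TRUE)
})

test_that("rank-deficient trait matrices give the minimum-norm solution", {
  set.seed(3)
  T_dup <- cbind(x = rnorm(5), y = 0)
  T_dup[, 2] <- T_dup[, 1] # duplicated trait column
  rownames(T_dup) <- paste0("s", 1:5)
  M <- mm(matrix(runif(15), 3, 5), samples = rownames(T_dup))
  fit <- expect_no_error(fit_mmlr(T_dup, M))
  C_oracle <- pracma::pinv(T_dup) %*% t(unclass(M))
  expect_equal(sqrt(sum(fit$coefficients^2)), sqrt(sum(C_oracle^2)),
    tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), unname(C_oracle), tolerance = 1e-8)
})

test_that("fit matches the SVD least-squares oracle on random instances", {
  for (s in 1:100) {
    set.seed(s)
    Tm <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10), paste0("t", 1:4)))
    M <- mm(matrix(runif(200), 20, 10), samples = rownames(Tm))
    fit <- fit_mmlr(Tm, M)
    C_oracle <- pracma::pinv(Tm) %*% t(unclass(M))
    expect_equal(unname(fit$coefficients), unname(C_oracle), tolerance = 1e-8)
  }
})

test_that("prediction is stateless and portable to external samples", {
  set.seed(4)
  Tm <- matrix(rnorm(24), 8, 3, dimnames = list(paste0("s", 1:8), paste0("t", 1:3)))
  M <- mm(matrix(runif(96), 12, 8), samples = rownames(Tm))
  fit <- fit_mmlr(Tm, M)
  external <- mm(matrix(runif(24), 12, 2), sites = rownames(M),
    samples = c("e1", "e2"))
  alone <- predict_traits(fit, external[, 1, drop = FALSE])
  batch <- predict_traits(fit, external)
  expect_equal(alone[1, -1], batch[1, -1], tolerance = 1e-12)
  # hand-checked small case against an independent pseudoinverse
  expect_equal(
    as.matrix(batch[, -1]),
    t(unclass(external)) %*% pracma::pinv(fit$coefficients),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  misaligned <- mm(matrix(runif(10), 5, 2), samples = c("e1", "e2"))
  expect_error(predict_traits(fit, misaligned), "do not align")
})

test_that("LOOCV isolates each fold from its own sample", {
  co <- tiny_cohort()
  keep <- 1:12
  m <- methyl_matrix(unclass(co$methylation)[, keep])
  md <- co$metadata[keep, ]
  tmat <- suppressWarnings(encode_traits(md, traits = c("age", "atg", "transplant")))
  panel <- suppressWarnings(loocv_episcores(tmat, m))
  # refit without sample i entirely: same score for sample i
  i <- 5
  fit_wo <- fit_mmlr(tmat[-i, ], methyl_matrix(unclass(m)[, -i]))
  pred_i <- predict_traits(fit_wo, methyl_matrix(unclass(m)[, i, drop = FALSE]))
  expect_equal(unlist(panel$scores[i, -1]), unlist(pred_i[1, -1]), tolerance = 1e-10)
  # perturbing sample i's traits never changes its own score
  tmat2 <- tmat
  tmat2[i, "age"] <- tmat2[i, "age"] + 30
  panel2 <- suppressWarnings(loocv_episcores(tmat2, m))
  expect_equal(panel$scores[i, -1], panel2$scores[i, -1], tolerance = 1e-10)
  # ... but does change other samples' scores (it enters their training)
  expect_false(isTRUE(all.equal(panel$scores[-i, -1], panel2$scores[-i, -1])))
})

test_that("grouped LOOCV holds a subject's paired samples out together", {
  co <- tiny_cohort()
  keep <- 1:16
  m <- methyl_matrix(unclass(co$methylation)[, keep])
  md <- co$metadata[keep, ]
  tmat <- suppressWarnings(encode_traits(md, traits = c("age", "atg", "transplant")))
  panel <- suppressWarnings(loocv_episcores(tmat, m,
    group_by_subject = TRUE, subjects = md$subject_id))
  # fold for subject 1 excludes both of its samples
  idx <- which(md$subject_id == md$subject_id[1])
  fit_wo <- fit_mmlr(tmat[-idx, ], methyl_matrix(unclass(m)[, -idx]))
  pred <- predict_traits(fit_wo, methyl_matrix(unclass(m)[, idx, drop = FALSE]))
  expect_equal(as.matrix(panel$scores[idx, -1]), as.matrix(pred[, -1]),
    tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("tie-aware AUC matches exhaustive pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # brute-force oracle: all positive/negative pairs, ties count 0.5
  scores <- c(0.3, 0.7, 0.7, 0.2, 0.9, 0.1)
  labels <- c(0, 1, 0, 0, 1, 1)
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  oracle <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
    ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(scores, labels)$auc, oracle)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # independent implementation on random data
  set.seed(10)
  s <- round(runif(40), 1)
  l <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(s, l)$auc,
    as.numeric(suppressMessages(pROC::auc(pROC::roc(l, s, quiet = TRUE)))))
})

test_that("group score test matches the exact rank-sum null tail", {
  # fully separated groups of 10 + 10: exact two-sided tail
  s <- c(rnorm(10, 10), rnorm(10, -10))
  l <- rep(c(1, 0), each = 10)
  res <- group_score_test(s, l)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # tie-heavy input gives a finite p
  expect_true(is.finite(group_score_test(rep(c(1, 1, 2), 4), rep(c(0, 1), 6))$p_value))
  expect_error(group_score_test(1:4, rep(1, 4)), "both classes")
})

test_that("actual-vs-predicted Spearman matrix matches rank-then-Pearson", {
  co <- tiny_cohort()
  keep <- 1:10
  m <- methyl_matrix(unclass(co$methylation)[, keep])
  tmat <- suppressWarnings(encode_traits(co$metadata[keep, ],
    traits = c("age", "atg")))
  panel <- suppressWarnings(loocv_episcores(tmat, m))
  tab <- actual_vs_predicted_correlation(tmat, panel)
  oracle <- cor(rank(tmat[, "age"]), rank(panel$scores$age))
  expect_equal(tab$rho[tab$actual == "age" & tab$predicted == "age"], oracle,
    tolerance = 1e-12)
  # perfect self-prediction
  fake <- panel
  fake$scores$age <- tmat[, "age"]
  tab2 <- actual_vs_predicted_correlation(tmat, fake)
  expect_equal(tab2$rho[tab2$actual == "age" & tab2$predicted == "age"], 1)
  # constant vector: NA with warning
  tmat_const <- cbind(tmat, flat = 1)
  expect_warning(tab3 <- actual_vs_predicted_correlation(tmat_const, panel),
    "constant")
  expect_true(all(is.na(tab3$rho[tab3$actual == "flat"])))
})

test_that("ridge logistic baseline matches a direct optimizer and its limits", {
  set.seed(20)
  n <- 20
  X <- matrix(rnorm(n * 5), 5, n, dimnames = list(paste0("chrS:", 1:5), paste0("s", 1:n)))
  X <- clip01((X + 3) / 6)
  m <- methyl_matrix(X)
  y <- rbinom(n, 1, stats::plogis(3 * (X[1, ] - 0.5)))
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  fit <- fit_penalized_logistic(m, y, penalty = 1, folds = 4)
  # oracle: generic numerical minimizer of the penalized log-loss
  nll <- function(b) {
    eta <- b[1] + drop(t(X) %*% b[-1])
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + 0.5 * sum(b[-1]^2)
  }
  opt <- optim(rep(0, 6), nll, method = "BFGS",
    control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-4)

  # ridge limit: coefficients vanish and full-model scores flatten, so the
  # tie convention puts the AUC at chance
  huge <- fit_penalized_logistic(m, y, penalty = 1e9, folds = 4)
  expect_lt(max(abs(huge$coefficients[-1])), 1e-6)
  full_scores <- stats::plogis(huge$coefficients[1] +
    drop(t(unclass(m)) %*% huge$coefficients[-1]))
  expect_lt(diff(range(full_scores)), 1e-5)
  expect_equal(roc_auc(round(full_scores, 3), y)$auc, 0.5)

  # separable one-site toy: perfect out-of-fold ranking
  m1 <- methyl_matrix(matrix(c(0.9, 0.85, 0.8, 0.95, 0.1, 0.2, 0.15, 0.05),
    nrow = 1, dimnames = list("chrS:1", paste0("s", 1:8))))
  y1 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(fit_penalized_logistic(m1, y1, penalty = 0.1, folds = 4)$auc, 1.0)
})

test_that("epi scores separate an injected binary trait", {
  co <- tiny_cohort()
  tmat <- encode_traits(co$metadata)
  panel <- loocv_episcores(tmat, co$methylation,
    group_by_subject = TRUE, subjects = co$metadata$subject_id)
  ev <- panel$evaluation
  expect_gt(ev$value[ev$trait == "atg"], 0.9)
  expect_gt(ev$value[ev$trait == "age"], 0.5)
  # group separation is significant
  p <- group_score_test(panel$scores$atg, tmat[, "atg"])$p_value
  expect_lt(p, 0.01)
})
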