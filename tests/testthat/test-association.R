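test_that("an exact linear site is recovered with the planted coefficient", {
  # y = 2 * atg exactly, other covariate orthogonal to atg
  atg <- rep(c(0, 1), each = 4)
  other <- rep(c(-1, 1), 4)
  design <- cbind(atg = atg, other = other)
  rownames(design) <- paste0("s", 1:8)
  vals <- rbind(0.1 + 0.2 * atg, rep(0.5, 8))
  m <- methyl_matrix(vals, site_ids = c("chrS:1", "chrS:2"),
    sample_ids = rownames(design))
  fit <- fit_sitewise_models(m, design)
  expect_equal(unname(fit$estimate["atg", "chrS:1"]), 0.2, tolerance = 1e-12)
  expect_lt(fit$p_value["atg", "chrS:1"], 1e-10)
  expect_equal(unname(fit$estimate["atg", "chrS:2"]), 0, tolerance = 1e-12)
})

test_that("site-wise OLS matches the normal-equation oracle and lm", {
  set.seed(6)
  n <- 6
  design <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  rownames(design) <- paste0("s", 1:n)
  m <- methyl_matrix(matrix(runif(3 * n), 3, n,
    dimnames = list(paste0("chrS:", 1:3), rownames(design))))
  fit <- fit_sitewise_models(m, design)
  X <- cbind(1, design)
  for (j in 1:3) {
    y <- unclass(m)[j, ]
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(fit$estimate[, j]), unname(drop(beta)), tolerance = 1e-10)
    lmfit <- summary(lm(y ~ design))
    expect_equal(unname(fit$p_value[, j]), unname(lmfit$coefficients[, 4]),
      tolerance = 1e-10)
    expect_equal(unname(fit$se[, j]), unname(lmfit$coefficients[, 2]),
      tolerance = 1e-10)
  }
})

test_that("random small designs match the oracle across many seeds", {
  for (s in 1:100) {
    set.seed(s)
    n <- 12
    design <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5), c = runif(n))
    rownames(design) <- paste0("s", 1:n)
    m <- methyl_matrix(matrix(runif(2 * n), 2, n,
      dimnames = list(c("chrS:1", "chrS:2"), rownames(design))))
    fit <- fit_sitewise_models(m, design)
    X <- cbind(1, design)
    beta <- solve(crossprod(X), crossprod(X, t(unclass(m))))
    expect_equal(unname(fit$estimate), unname(beta), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs name the collinear columns", {
  design <- cbind(a = rep(1, 8), b = rep(1, 8))
  rownames(design) <- paste0("s", 1:8)
  m <- methyl_matrix(matrix(runif(8), 1, 8,
    dimnames = list("chrS:1", rownames(design))))
  expect_error(fit_sitewise_models(m, design), "collinear")
})

test_that("null-site p-values are uniform", {
  set.seed(77)
  n <- 60
  design <- cbind(atg = rbinom(n, 1, 0.5), age = runif(n, 25, 70))
  rownames(design) <- paste0("s", 1:n)
  vals <- clip01(matrix(rnorm(1000 * n, 0.5, 0.1), 1000, n))
  m <- methyl_matrix(vals, site_ids = paste0("chrS:", 1:1000),
    sample_ids = rownames(design))
  fit <- fit_sitewise_models(m, design)
  ks <- stats::ks.test(fit$p_value["atg", ], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the hand-computed step-up values", {
  # p(i) * n / i, then cumulative minimum from the largest rank down
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  # order invariance
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("trait-associated site selection honors alpha and direction", {
  co <- tiny_cohort()
  fr <- as_cell_fractions(co$truth$true_cell_fractions)
  pcs <- compute_cell_pcs(fr, 5)
  design <- encode_traits(co$metadata, cell_pcs = pcs)
  fit <- fit_sitewise_models(co$methylation, design)
  truth <- co$truth$true_effect_sites$atg$site

  sel <- select_trait_associated_sites(fit, "atg", direction = "positive")
  expect_gt(mean(truth %in% sel$site), 0.9) # recall
  expect_lt(mean(!sel$site %in% truth), 0.1) # false discovery share

  # only positive effects were planted: the negative set is near-empty
  neg <- select_trait_associated_sites(fit, "atg", direction = "negative")
  expect_lt(nrow(neg), 3)
  expect_equal(nrow(select_trait_associated_sites(fit, "atg", alpha = 0)), 0L)
  expect_error(select_trait_associated_sites(fit, "nope"), "unknown trait")
})

test_that("recall of planted sites is non-decreasing in effect size", {
  recall_at <- function(effect, seed = 91) {
    cfg <- sim_config(n_subjects = 40, n_sites = 2000, paired = FALSE,
      seed = seed, trait_effects = list(atg = list(n_sites = 60, effect = effect)))
    co <- simulate_cohort(cfg, simulate_reference_panel(cfg))
    pcs <- compute_cell_pcs(as_cell_fractions(co$truth$true_cell_fractions), 5)
    design <- encode_traits(co$metadata, cell_pcs = pcs)
    fit <- fit_sitewise_models(co$methylation, design)
    sel <- select_trait_associated_sites(fit, "atg", direction = "positive")
    mean(co$truth$true_effect_sites$atg$site %in% sel$site)
  }
  r <- vapply(c(0.02, 0.08, 0.20), recall_at, 0)
  expect_true(all(diff(r) >= 0))
  expect_gt(r[3], 0.95)
})

test_that("methylation-expression filter keeps planted anticorrelated pairs", {
  co <- tiny_cohort()
  strong <- simulate_expression(co, b = 6, expr_noise_sd = 0.2)
  hits <- methylation_expression_correlation(co$methylation,
    strong$expression, strong$mapping)
  expect_gt(nrow(hits), 0.9 * nrow(strong$mapping))
  expect_true(all(hits$r < -0.3))
  expect_true(all(hits$direction == "down"))

  # null expression passes at roughly the alpha level
  null_map <- tibble::tibble(
    site = strong$mapping$site,
    gene = sprintf("N%04d", seq_len(nrow(strong$mapping)))
  )
  null_map <- null_map[seq_len(min(100, nrow(null_map))), ]
  null_hits <- methylation_expression_correlation(co$methylation,
    strong$expression, null_map)
  expect_lt(nrow(null_hits) / nrow(null_map), 0.12)
})

test_that("a perfectly linear pair reaches |R| = 1 and tiny overlaps error", {
  vals <- matrix(seq(0.1, 0.8, length.out = 8), 1, 8,
    dimnames = list("chrS:1", paste0("s", 1:8)))
  m <- methyl_matrix(vals)
  expr <- matrix(10 - 5 * vals, 1, 8, dimnames = list("G1", colnames(vals)))
  map <- tibble::tibble(site = "chrS:1", gene = "G1")
  hits <- methylation_expression_correlation(m, expr, map)
  expect_equal(hits$r, -1, tolerance = 1e-12)
  expect_error(
    methylation_expression_correlation(m[, 1:2, drop = FALSE],
      expr[, 1:2, drop = FALSE], map),
    "at least 3 shared samples"
  )
})
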