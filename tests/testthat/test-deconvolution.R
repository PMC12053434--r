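test_that("DMR caller recovers planted blocks and nothing else", {
  panel <- tiny_panel()
  markers <- call_celltype_dmrs(panel)
  truth <- panel$true_dmrs
  # every planted block recovered by a same-celltype overlapping call
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    r <- markers$regions
    any(r$celltype == truth$label[i] &
      r$start < truth$end[i] & r$end > truth$start[i])
  }, TRUE)
  expect_true(all(hit))
  # no call outside planted blocks
  outside <- vapply(seq_len(nrow(markers$regions)), function(i) {
    r <- markers$regions[i, ]
    !any(truth$label == r$celltype & truth$start < r$end & truth$end > r$start)
  }, TRUE)
  expect_equal(sum(outside), 0L)
  expect_true(all(markers$regions$delta <= -0.30))
  expect_true(all(markers$regions$p_adj < 0.05))
  expect_true(all(markers$regions$end - markers$regions$start > 500))
})

test_that("length and delta criteria reject undersized or shallow blocks", {
  # 400 bp planted blocks: deep enough, but too short
  cfg_short <- tiny_config(seed = 21, dmr_block_length_bp = 400)
  short_panel <- simulate_reference_panel(cfg_short)
  expect_equal(nrow(call_celltype_dmrs(short_panel, min_length_bp = 500)$regions), 0L)
  # same panel accepted when the length criterion matches the blocks
  expect_gt(nrow(call_celltype_dmrs(short_panel, min_length_bp = 400)$regions), 0L)

  # shallow blocks (-0.10) fail the delta criterion
  cfg_shallow <- tiny_config(seed = 22, dmr_delta = -0.10)
  shallow_panel <- simulate_reference_panel(cfg_shallow)
  expect_equal(nrow(call_celltype_dmrs(shallow_panel, delta_threshold = -0.30)$regions), 0L)
})

test_that("DMR caller rejects degenerate panels", {
  panel <- tiny_panel()
  solo <- panel
  keep <- solo$replicate_celltype == solo$celltypes[1]
  solo$replicates <- solo$replicates[keep, , drop = FALSE]
  solo$replicate_celltype <- solo$replicate_celltype[keep]
  expect_error(call_celltype_dmrs(solo), "at least 2 cell types")

  single_rep <- panel
  first_of <- !duplicated(single_rep$replicate_celltype)
  single_rep$replicates <- single_rep$replicates[first_of, , drop = FALSE]
  single_rep$replicate_celltype <- single_rep$replicate_celltype[first_of]
  expect_error(call_celltype_dmrs(single_rep), "at least 2 replicates")
})

test_that("pure reference profiles deconvolve to one-hot fractions", {
  panel <- tiny_panel()
  markers <- call_celltype_dmrs(panel)
  pure <- methyl_matrix(t(panel$profiles),
    site_ids = panel$site_ids, sample_ids = panel$celltypes)
  f <- fractions_matrix(estimate_cell_fractions(pure, panel, markers))
  expect_equal(unname(f), diag(length(panel$celltypes)), tolerance = 1e-8)
})

test_that("a two-component mixture is recovered and matches a grid-search oracle", {
  panel <- tiny_panel()
  markers <- call_celltype_dmrs(panel)
  sites <- sort(unique(unlist(markers$sites)))
  set.seed(101)
  mix <- 0.6 * panel$profiles["B", ] + 0.4 * panel$profiles["CD4T", ]
  noisy <- clip01(mix + rnorm(length(mix), 0, 0.02))
  m <- methyl_matrix(matrix(noisy, ncol = 1,
    dimnames = list(panel$site_ids, "mix1")))
  f <- fractions_matrix(estimate_cell_fractions(m, panel, markers))
  expect_lt(abs(f[1, "B"] - 0.6), 0.05)
  expect_lt(abs(f[1, "CD4T"] - 0.4), 0.05)

  # oracle: exhaustive search over the B/CD4T 2-simplex at 0.01 resolution
  R <- t(panel$profiles[c("B", "CD4T"), sites])
  y <- unclass(m)[sites, 1]
  grid <- seq(0, 1, by = 0.01)
  rss <- vapply(grid, function(a) sum((R %*% c(a, 1 - a) - y)^2), 0)
  best <- grid[which.min(rss)]
  two_ct <- f[1, c("B", "CD4T")] / sum(f[1, c("B", "CD4T")])
  expect_lt(abs(two_ct[["B"]] - best), 0.02)
})

test_that("fraction recovery over Dirichlet mixtures is accurate on average", {
  cfg <- tiny_config(seed = 33, noise_sd = 0.02, trait_effects = list())
  panel <- simulate_reference_panel(cfg)
  co <- simulate_cohort(cfg, panel)
  markers <- call_celltype_dmrs(panel)
  f <- fractions_matrix(estimate_cell_fractions(co$methylation, panel, markers))
  mae <- colMeans(abs(f - co$truth$true_cell_fractions))
  expect_true(all(mae < 0.05))
})

test_that("degenerate deconvolution inputs are reported", {
  panel <- tiny_panel()
  markers <- call_celltype_dmrs(panel)
  # duplicated reference profiles: collinearity warning, fit still returns
  dup <- panel
  dup$profiles["CD8T", ] <- dup$profiles["CD4T", ]
  pure <- methyl_matrix(t(dup$profiles)[, 1, drop = FALSE],
    site_ids = dup$site_ids, sample_ids = "s1")
  expect_warning(estimate_cell_fractions(pure, dup, markers), "collinear")

  # no shared marker sites
  renamed <- methyl_matrix(unclass(pure),
    site_ids = paste0("chrX:", seq_len(nrow(pure))), sample_ids = "s1")
  expect_error(estimate_cell_fractions(renamed, panel, markers), "no marker sites")

  # all-zero NNLS solution under normalization
  zero_panel <- panel
  zero_panel$profiles[] <- 1 # reference fully methylated, sample fully unmethylated
  zmat <- methyl_matrix(matrix(0, length(panel$site_ids), 1,
    dimnames = list(panel$site_ids, "z")))
  expect_error(
    suppressWarnings(estimate_cell_fractions(zmat, zero_panel, markers)),
    "degenerate fit"
  )
})

test_that("adding a truly present cell type never increases the NNLS residual", {
  panel <- tiny_panel()
  markers <- call_celltype_dmrs(panel)
  sites <- sort(unique(unlist(markers$sites)))
  set.seed(55)
  for (rep in 1:5) {
    w <- as.numeric(.rdirichlet_test(1, rep(2, 3)))
    y <- drop(t(panel$profiles[c("B", "CD4T", "NK"), sites]) %*% w) +
      rnorm(length(sites), 0, 0.02)
    rss <- function(cts) {
      R <- t(panel$profiles[cts, sites, drop = FALSE])
      f <- pracma::lsqnonneg(R, y)$x
      sum((R %*% f - y)^2)
    }
    expect_lte(rss(c("B", "CD4T", "NK")), rss(c("B", "CD4T")) + 1e-10)
  }
})

test_that("cell-type PCs behave like a centred eigendecomposition", {
  # constant fractions: all scores zero
  const <- as_cell_fractions(matrix(1 / 3, 5, 3,
    dimnames = list(paste0("s", 1:5), c("A", "B", "C"))))
  pcs <- compute_cell_pcs(const, 2)
  expect_true(all(abs(as.matrix(pcs[, -1])) < 1e-12))

  # rank-1 variation: PC1 explains ~all variance
  v <- seq(0.1, 0.5, length.out = 6)
  f1 <- cbind(A = v, B = 0.5 - v / 2, C = 0.5 - v / 2)
  rownames(f1) <- paste0("s", 1:6)
  p1 <- compute_cell_pcs(as_cell_fractions(f1), 2)
  ve <- attr(p1, "var_explained")
  expect_gt(ve[1], 0.999)

  # toy matrix matches brute-force eigendecomposition of the covariance
  set.seed(9)
  f2 <- matrix(runif(15), 5, 3, dimnames = list(paste0("s", 1:5), c("A", "B", "C")))
  p2 <- compute_cell_pcs(as_cell_fractions(f2, normalized = FALSE), 2)
  cf <- scale(f2, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(cf) / (nrow(f2) - 1))
  scores_oracle <- cf %*% eig$vectors[, 1:2]
  got <- as.matrix(p2[, c("cell_pc1", "cell_pc2")])
  for (j in 1:2) {
    expect_equal(abs(got[, j]), unname(abs(scores_oracle[, j])), tolerance = 1e-8)
  }
  expect_error(compute_cell_pcs(as_cell_fractions(f2), 3), "smaller than")
})
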