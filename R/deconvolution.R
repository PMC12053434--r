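#' Call cell-type-specific hypomethylated marker regions (one-vs-all)
#'
#' For each cell type, the per-site delta is the mean over its replicates
#' minus the pooled mean over all other replicates. Candidate regions are
#' maximal runs of consecutive sites with `delta <= delta_threshold`
#' (broken where the gap between neighbouring CpGs exceeds `gap_bp`), kept
#' when their genomic span (last minus first position) reaches
#' `min_length_bp`. Each candidate is tested by a Wilcoxon rank-sum test of
#' the cell type's replicate region means against all other replicates'
#' region means, and p-values are Benjamini-Hochberg adjusted across all
#' candidates of all cell types; regions with adjusted p below `fdr` are
#' reported. Only hypomethylated (negative-delta) markers are called.
#'
#' @param panel a `reference_panel` (see [simulate_reference_panel()] for
#'   the synthetic constructor; any object with `$replicates`,
#'   `$replicate_celltype`, `$site_ids`, `$positions`, `$celltypes` works).
#' @param min_length_bp minimum region span (default 500 bp).
#' @param delta_threshold per-site one-vs-all delta ceiling (fraction
#'   scale; default -0.30, i.e. 30 percentage points below the rest).
#' @param fdr BH-adjusted p-value cutoff (default 0.05).
#' @param gap_bp maximum gap between consecutive sites within one region.
#' @return a `marker_set`: `$regions` tibble (chrom, start, end — BED
#'   convention —, celltype, n_sites, delta, p, p_adj) and `$sites`, a
#'   named list of member site keys per cell type.
#' @export
call_celltype_dmrs <- function(panel, min_length_bp = 500,
                               delta_threshold = -0.30, fdr = 0.05,
                               gap_bp = 300) {
  reps <- panel$replicates
  ct_of <- panel$replicate_celltype
  celltypes <- unique(ct_of)
  if (length(celltypes) < 2) abort("one-vs-all comparison needs at least 2 cell types")
  if (min(table(ct_of)) < 2) abort("each cell type needs at least 2 replicates")
  pos <- panel$positions
  ord <- order(pos)
  pos <- pos[ord]
  sites <- panel$site_ids[ord]
  reps <- reps[, ord, drop = FALSE]

  candidates <- list()
  for (tc in celltypes) {
    own <- ct_of == tc
    delta <- colMeans(reps[own, , drop = FALSE]) - colMeans(reps[!own, , drop = FALSE])
    hit <- delta <= delta_threshold
    if (!any(hit)) next
    # run ids: break at non-hits and at gaps > gap_bp
    new_run <- c(TRUE, diff(pos) > gap_bp)
    run_id <- cumsum(new_run | c(TRUE, !hit[-length(hit)]))
    for (r in split(which(hit), run_id[hit])) {
      span <- pos[r[length(r)]] - pos[r[1]]
      if (span < min_length_bp) next
      own_means <- rowMeans(reps[own, r, drop = FALSE])
      other_means <- rowMeans(reps[!own, r, drop = FALSE])
      p <- suppressWarnings(
        wilcox.test(own_means, other_means, exact = FALSE)$p.value
      )
      candidates[[length(candidates) + 1L]] <- tibble::tibble(
        chrom = parse_site_ids(sites[r[1]])$chrom,
        start = pos[r[1]] - 1L, end = pos[r[length(r)]],
        celltype = tc, n_sites = length(r),
        delta = mean(delta[r]), p = p,
        site_keys = list(sites[r])
      )
    }
  }
  if (!length(candidates)) {
    regions <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      celltype = character(), n_sites = integer(), delta = numeric(),
      p = numeric(), p_adj = numeric()
    )
    return(structure(list(regions = regions,
      sites = setNames(rep(list(character()), length(celltypes)), celltypes)),
      class = "marker_set"))
  }
  cand <- dplyr::bind_rows(candidates)
  cand$p_adj <- p.adjust(cand$p, method = "BH")
  keep <- cand[cand$p_adj < fdr, , drop = FALSE]
  site_lists <- lapply(setNames(nm = celltypes), function(tc) {
    sort(unique(unlist(keep$site_keys[keep$celltype == tc])))
  })
  keep$site_keys <- NULL
  structure(list(regions = keep, sites = site_lists), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf(
    "<marker_set> %d regions over %d cell types (%d marker sites)\n",
    nrow(x$regions), sum(lengths(x$sites) > 0), length(unlist(x$sites))
  ))
  invisible(x)
}

#' Export marker regions as a region set
#'
#' @param markers a `marker_set`.
#' @return a [region_set()] (label = cell type, score = region delta),
#'   ready for [write_regions_bed()].
#' @export
marker_regions <- function(markers) {
  r <- markers$regions
  region_set(r$chrom, r$start, r$end, r$celltype, r$delta)
}

#' Estimate cell-type fractions by nonnegative least squares
#'
#' Restricts the reference cell-type mean profiles and each sample to the
#' union of marker sites and solves `min || R f - m ||^2, f >= 0`
#' (Lawson-Hanson NNLS). Raw coefficients need not sum to one; with
#' `normalize = TRUE` (the default) each sample's coefficients are divided
#' by their sum so they read directly as mixture fractions, and the raw
#' sum is kept in the `raw_sum` column.
#'
#' @param m a [methyl_matrix()] (sites x samples) or a single named sample
#'   vector.
#' @param panel a `reference_panel` (uses `$profiles`, the cell-type
#'   means).
#' @param markers a `marker_set` from [call_celltype_dmrs()]; `NULL` uses
#'   all shared sites.
#' @param normalize divide coefficients by their sum (error on an all-zero
#'   fit).
#' @return a `cell_fractions` tibble: `sample_id`, one column per cell
#'   type, `raw_sum`.
#' @export
estimate_cell_fractions <- function(m, panel, markers = NULL, normalize = TRUE) {
  if (!is.matrix(m)) m <- matrix(m, ncol = 1, dimnames = list(names(m), "sample1"))
  sites_needed <- if (is.null(markers)) rownames(m) else sort(unique(unlist(markers$sites)))
  if (!length(sites_needed)) abort("empty marker site set")
  shared <- intersect(sites_needed, intersect(rownames(m), colnames(panel$profiles)))
  if (!length(shared)) abort("no marker sites shared with the sample matrix")
  if (length(shared) < 0.5 * length(sites_needed)) {
    warn(sprintf(
      "only %d/%d marker sites present in the sample matrix",
      length(shared), length(sites_needed)
    ))
  }
  R <- t(panel$profiles[, shared, drop = FALSE]) # sites x celltypes
  if (qr(R)$rank < ncol(R)) {
    warn("reference profiles are collinear on the marker sites; fraction split among collinear types is arbitrary")
  }
  Y <- unclass(m)[shared, , drop = FALSE]
  fit_one <- function(y) pracma::lsqnonneg(R, y)$x
  f <- t(apply(Y, 2, fit_one))
  colnames(f) <- colnames(R)
  raw_sum <- rowSums(f)
  if (normalize) {
    if (any(raw_sum == 0)) {
      abort(sprintf("degenerate fit: all-zero NNLS solution for sample '%s'",
        colnames(Y)[which(raw_sum == 0)[1]]))
    }
    f <- f / raw_sum
  }
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(Y)),
    tibble::as_tibble(f),
    tibble::tibble(raw_sum = raw_sum)
  )
  attr(out, "normalized") <- normalize
  attr(out, "celltypes") <- colnames(R)
  class(out) <- c("cell_fractions", class(out))
  out
}

#' Wrap a sample x celltype fraction matrix as a `cell_fractions` tibble
#'
#' Useful for feeding externally known (e.g. ground-truth) mixture
#' fractions into [compute_cell_pcs()].
#'
#' @param f numeric matrix, samples in rows (rownames = sample ids),
#'   cell types in columns.
#' @param normalized whether rows are already mixture fractions summing
#'   to 1.
#' @return a `cell_fractions` tibble.
#' @export
as_cell_fractions <- function(f, normalized = TRUE) {
  stopifnot(is.matrix(f), !is.null(rownames(f)), !is.null(colnames(f)))
  if (any(f < 0)) abort("cell fractions must be nonnegative")
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(f)),
    tibble::as_tibble(f),
    tibble::tibble(raw_sum = rowSums(f))
  )
  attr(out, "normalized") <- normalized
  attr(out, "celltypes") <- colnames(f)
  class(out) <- c("cell_fractions", class(out))
  out
}

#' Extract the numeric fraction matrix from a `cell_fractions` tibble
#'
#' @param fractions a `cell_fractions` tibble.
#' @return sample x celltype numeric matrix.
#' @export
fractions_matrix <- function(fractions) {
  ct <- attr(fractions, "celltypes")
  f <- as.matrix(fractions[, ct, drop = FALSE])
  rownames(f) <- fractions$sample_id
  f
}

#' Principal components of cell-type fractions
#'
#' Column-centred PCA (no scaling) of the fraction matrix, used as
#' cell-composition covariates downstream. Sign convention: within each
#' component the loading of largest magnitude is made positive, so scores
#' are reproducible across platforms.
#'
#' @param fractions a `cell_fractions` tibble.
#' @param n_pcs number of components (must be < number of cell types).
#' @return tibble: `sample_id`, `cell_pc1` ... `cell_pc<n>`; the
#'   proportion of variance explained is attached as attribute
#'   `"var_explained"`.
#' @export
compute_cell_pcs <- function(fractions, n_pcs = 2) {
  f <- fractions_matrix(fractions)
  if (n_pcs >= ncol(f)) abort("n_pcs must be smaller than the number of cell types")
  if (nrow(f) < n_pcs + 1) abort("need at least n_pcs + 1 samples")
  pc <- prcomp(f, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("cell_pc", seq_len(k))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = fractions$sample_id),
    tibble::as_tibble(scores))
  tot <- sum(pc$sdev^2)
  attr(out, "var_explained") <- if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
  out
}
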