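#' Moore-Penrose pseudoinverse
#'
#' Computed from the singular value decomposition, zeroing singular values
#' below `max(dim(A)) * eps * sigma_max` (the conventional cutoff), so
#' rank-deficient systems return the minimum-norm least-squares solution.
#'
#' @param a numeric matrix.
#' @param tol singular-value cutoff; defaults to the SVD-based rule above.
#' @return the pseudoinverse, with `dim = rev(dim(a))`.
#' @export
pseudoinverse <- function(a, tol = NULL) {
  stopifnot(is.matrix(a), is.numeric(a))
  if (any(!is.finite(a))) abort("matrix contains non-finite values")
  s <- svd(a)
  if (is.null(tol)) {
    tol <- max(dim(a)) * .Machine$double.eps * max(s$d, 0)
  }
  keep <- s$d > tol
  if (!any(keep)) {
    return(matrix(0, ncol(a), nrow(a)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Deterministic per-component seed streams: one root seed expands through a
# fixed offset table so adding a generator never perturbs existing streams.
.seed_offsets <- c(
  panel = 1L, cohort = 2L, survival = 3L, expression = 4L,
  permutation = 5L, moderation = 6L, pipeline = 7L, folds = 8L
)

derive_seed <- function(root_seed, stream, index = 0L) {
  stopifnot(stream %in% names(.seed_offsets))
  root_seed <- as.integer(root_seed)
  off <- .seed_offsets[[stream]]
  # stay well below .Machine$integer.max
  as.integer((abs(root_seed) * 97L + off * 7919L + as.integer(index) * 104729L) %%
    2000000011)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# site keys are "chrom:pos", pos 1-based
make_site_ids <- function(chrom, pos) paste0(chrom, ":", pos)

parse_site_ids <- function(site_ids) {
  parts <- strsplit(site_ids, ":", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    abort(paste0(
      "malformed site key(s): ",
      paste(head(site_ids[bad], 3), collapse = ", "),
      " (expected 'chrom:pos')"
    ))
  }
  tibble::tibble(
    site = site_ids,
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L))
  )
}
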