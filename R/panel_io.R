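#' Write a reference panel's replicate profiles to TSV
#'
#' One row per site (`site` key column), one column per replicate named
#' `<celltype>.rep<k>`. [read_reference_panel()] reconstructs the panel
#' from this layout, recomputing cell-type mean profiles as replicate
#' means.
#'
#' @param panel a `reference_panel`.
#' @param path output file path.
#' @export
write_reference_panel <- function(panel, path) {
  df <- dplyr::bind_cols(
    tibble::tibble(site = panel$site_ids),
    tibble::as_tibble(t(round(panel$replicates, 6)))
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a reference panel from TSV
#'
#' @param path file written by [write_reference_panel()] (or matching its
#'   layout: `site` column plus `<celltype>.rep<k>` replicate columns).
#' @return a `reference_panel` whose `$profiles` are replicate means.
#' @export
read_reference_panel <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(), site = readr::col_character()
  ), progress = FALSE)
  rep_cols <- setdiff(names(df), "site")
  if (!length(rep_cols) || !all(grepl("\\.rep\\d+$", rep_cols))) {
    abort("panel columns must be named <celltype>.rep<k>")
  }
  reps <- t(as.matrix(df[rep_cols]))
  colnames(reps) <- df$site
  if (any(!is.finite(reps) | reps < 0 | reps > 1)) {
    abort("panel methylation values must be complete fractions in [0, 1]")
  }
  ct_of <- sub("\\.rep\\d+$", "", rep_cols)
  celltypes <- unique(ct_of)
  profiles <- do.call(rbind, lapply(celltypes, function(tc) {
    colMeans(reps[ct_of == tc, , drop = FALSE])
  }))
  rownames(profiles) <- celltypes
  coords <- parse_site_ids(df$site)
  structure(list(
    celltypes = celltypes, site_ids = df$site, positions = coords$pos,
    profiles = profiles, replicates = reps, replicate_celltype = ct_of,
    true_dmrs = NULL, marker_site_idx = integer(0), config = NULL
  ), class = "reference_panel")
}
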