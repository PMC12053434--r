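#' Construct a validated methylation matrix
#'
#' A `methyl_matrix` is a dense numeric matrix of methylation fractions with
#' CpG sites as rows (keys `"chrom:pos"`, 1-based position) and samples as
#' columns. Every entry must be a finite fraction in \[0, 1\] and both id
#' sets must be unique — the container is complete by contract, matching a
#' coverage-filtered aggregate matrix (no imputation happens downstream).
#'
#' @param values numeric matrix, sites x samples.
#' @param site_ids,sample_ids row / column identifiers; default to the
#'   dimnames of `values`.
#' @return a `methyl_matrix` (a classed numeric matrix).
#' @export
methyl_matrix <- function(values, site_ids = rownames(values),
                          sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(site_ids) || is.null(sample_ids)) {
    abort("site and sample identifiers are required")
  }
  if (nrow(values) == 0L) abort("no sites: methylation matrix is empty")
  if (ncol(values) == 0L) abort("no samples: methylation matrix is empty")
  if (anyDuplicated(site_ids)) {
    abort(paste0("duplicate site key: ", site_ids[duplicated(site_ids)][1]))
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1]))
  }
  bad <- which(!is.finite(values) | values < 0 | values > 1)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(values))
    abort(sprintf(
      "methylation value out of [0, 1] (or missing) at site '%s', sample '%s'",
      site_ids[i[1]], sample_ids[i[2]]
    ))
  }
  dimnames(values) <- list(site = site_ids, sample = sample_ids)
  class(values) <- c("methyl_matrix", class(values))
  values
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf(
    "<methyl_matrix> %d sites x %d samples (fractions in [0, 1])\n",
    nrow(x), ncol(x)
  ))
  invisible(x)
}

#' Read a methylation-fraction matrix from TSV
#'
#' Expects a tab-delimited file whose first column (`site`) holds
#' `"chrom:pos"` keys and whose remaining columns are one sample each.
#' Values are validated as complete fractions in \[0, 1\]; row and column
#' order are preserved.
#'
#' @param path file path.
#' @param drop_incomplete if `TRUE`, rows with missing cells are dropped
#'   with a message instead of raising an error.
#' @return a [methyl_matrix()].
#' @export
read_methylation_matrix <- function(path, drop_incomplete = FALSE) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    site = readr::col_character()
  ), progress = FALSE)
  if (!"site" %in% names(df)) {
    abort("first column of a methylation matrix must be named 'site'")
  }
  if (nrow(df) == 0L) abort("no sites: methylation matrix is empty")
  values <- as.matrix(df[setdiff(names(df), "site")])
  rownames(values) <- df$site
  if (drop_incomplete) {
    incomplete <- rowSums(!is.finite(values)) > 0
    if (any(incomplete)) {
      inform(sprintf("dropping %d incomplete site(s)", sum(incomplete)))
      values <- values[!incomplete, , drop = FALSE]
    }
  } else if (anyNA(values)) {
    i <- arrayInd(which(is.na(values))[1], dim(values))
    abort(sprintf(
      "missing methylation value at site '%s', sample '%s' (matrix must be complete)",
      rownames(values)[i[1]], colnames(values)[i[2]]
    ))
  }
  methyl_matrix(values)
}

#' Write a methylation matrix to TSV
#'
#' Inverse of [read_methylation_matrix()]; fractions are written with six
#' decimal places so round-trips are exact at that precision.
#'
#' @param m a [methyl_matrix()].
#' @param path output file path.
#' @export
write_methylation_matrix <- function(m, path) {
  stopifnot(inherits(m, "methyl_matrix"))
  df <- tibble::as_tibble(round(unclass(m), 6), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(site = rownames(m)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

.meta_levels <- list(
  sex = c(M = "m", F = "f"),
  cmv = c(positive = "positive", negative = "negative"),
  transplant = c(pre = "pre", post = "post"),
  atg = c(yes = "yes", no = "no"),
  infection_risk = c(yes = "yes", no = "no")
)

.normalize_level <- function(x, field) {
  allowed <- .meta_levels[[field]]
  key <- tolower(trimws(as.character(x)))
  bad <- !is.na(key) & !key %in% allowed
  if (any(bad)) {
    abort(sprintf(
      "unknown value '%s' for field '%s' (allowed: %s)",
      x[bad][1], field, paste(names(allowed), collapse = ", ")
    ))
  }
  names(allowed)[match(key, allowed)]
}

.parse_yes_no <- function(x, field) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[key %in% c("yes", "true", "1")] <- TRUE
  out[key %in% c("no", "false", "0")] <- FALSE
  bad <- !is.na(key) & key != "" & is.na(out)
  if (any(bad)) {
    abort(sprintf("unknown value '%s' for field '%s' (allowed: yes, no)", x[bad][1], field))
  }
  out
}

#' Read a sample metadata table from TSV
#'
#' Required columns: `subject_id`, `sample_id`, `age`, `sex` (M/F), `cmv`
#' (positive/negative), `transplant` (pre/post), `atg` (yes/no),
#' `infection_risk` (yes/no). Optional: `induction_arm` (yes/no, the
#' subject-level assignment), `days_to_infection`, `event_observed`
#' (yes/no), and any number of `ancestry_pc*` columns. Categorical values
#' are matched case-insensitively; a subject may contribute paired pre/post
#' samples.
#'
#' @param path file path.
#' @return a tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  required <- c(
    "subject_id", "sample_id", "age", "sex", "cmv", "transplant",
    "atg", "infection_risk"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("metadata is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in metadata")
  out <- tibble::tibble(
    subject_id = df$subject_id,
    sample_id = df$sample_id,
    age = as.numeric(df$age),
    sex = .normalize_level(df$sex, "sex"),
    cmv = .normalize_level(df$cmv, "cmv"),
    transplant = .normalize_level(df$transplant, "transplant"),
    atg = .normalize_level(df$atg, "atg"),
    infection_risk = .normalize_level(df$infection_risk, "infection_risk")
  )
  if (any(is.na(out$age)) || any(out$age < 0)) {
    abort(sprintf(
      "invalid age for sample '%s' (must be a nonnegative number)",
      out$sample_id[which(is.na(out$age) | out$age < 0)[1]]
    ))
  }
  if ("induction_arm" %in% names(df)) {
    out$induction_arm <- .normalize_level(df$induction_arm, "atg")
  }
  out$days_to_infection <- if ("days_to_infection" %in% names(df)) {
    as.numeric(df$days_to_infection)
  } else {
    NA_real_
  }
  out$event_observed <- if ("event_observed" %in% names(df)) {
    .parse_yes_no(df$event_observed, "event_observed")
  } else {
    NA
  }
  bad <- !is.na(out$event_observed) & out$event_observed & is.na(out$days_to_infection)
  if (any(bad)) {
    abort(sprintf(
      "sample '%s' has event_observed = yes but no days_to_infection",
      out$sample_id[bad][1]
    ))
  }
  pc_cols <- grep("^ancestry_pc", names(df), value = TRUE)
  for (pc in pc_cols) out[[pc]] <- as.numeric(df[[pc]])
  out
}

#' Write a sample metadata table to TSV
#'
#' @param metadata a metadata tibble as produced by [read_sample_metadata()]
#'   or [simulate_cohort()].
#' @param path output file path.
#' @export
write_sample_metadata <- function(metadata, path) {
  df <- metadata
  if ("event_observed" %in% names(df)) {
    df$event_observed <- ifelse(is.na(df$event_observed), NA_character_,
      ifelse(df$event_observed, "yes", "no"))
  }
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Construct a region set
#'
#' Regions use the BED convention throughout: 0-based, half-open
#' `[start, end)` coordinates, so `end - start` is the region width in bp.
#'
#' @param chrom,start,end,label,score region fields (vectors of equal length).
#' @return a `region_set` tibble.
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), label = character(),
                       score = numeric()) {
  out <- tibble::tibble(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), label = as.character(label),
    score = as.numeric(score)
  )
  if (any(out$start >= out$end)) {
    abort("region start must be strictly less than end (0-based half-open)")
  }
  class(out) <- c("region_set", class(out))
  out
}

#' Write regions as BED6
#'
#' Columns: chrom, start, end, name (label), score, strand (`"."`). No
#' header, 0-based half-open coordinates.
#'
#' @param regions a [region_set()] (or tibble with the same columns).
#' @param path output file path.
#' @export
write_regions_bed <- function(regions, path) {
  regions <- region_set(
    regions$chrom, regions$start, regions$end,
    regions$label, regions$score
  )
  bed <- tibble::tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = regions$label, score = regions$score, strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 file as a region set
#'
#' @param path file path.
#' @return a [region_set()].
#' @export
read_regions_bed <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE
  )
  region_set(df$chrom, df$start, df$end, df$name, df$score)
}

#' Check that every matrix sample has metadata
#'
#' Samples present in the metadata but absent from the matrix are allowed
#' (with a warning); the reverse is an error, since downstream models need
#' complete trait information.
#'
#' @param m a [methyl_matrix()].
#' @param metadata a metadata tibble.
#' @return the metadata rows matching the matrix columns, in matrix order.
#' @export
join_metadata <- function(m, metadata) {
  missing <- setdiff(colnames(m), metadata$sample_id)
  if (length(missing)) {
    abort(paste0(
      "sample(s) in matrix without metadata: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  extra <- setdiff(metadata$sample_id, colnames(m))
  if (length(extra)) {
    warn(sprintf("%d metadata sample(s) absent from the matrix are ignored", length(extra)))
  }
  metadata[match(colnames(m), metadata$sample_id), , drop = FALSE]
}
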