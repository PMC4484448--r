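#' Read and write peptide-spectrum-match tables
#'
#' Tab-delimited, one row per PSM, with the exact column order
#' `spectrum_id`, `peptide`, `protein`, `score`, `identity_threshold`,
#' `is_decoy` (0/1), `sample`. The reader validates column presence and
#' types, converts `is_decoy` to logical, and reports the rows of malformed
#' records; the writer emits the same dialect so tables round-trip
#' losslessly.
#'
#' @param path File path.
#' @param psms A PSM tibble (see [filter_significant_psms()]).
#' @return `read_psm_table()` returns a PSM tibble; `write_psm_table()`
#'   returns `path` invisibly.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read PSM table '%s'.", path))
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(psm_columns, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "PSM table '%s' is missing column(s): %s.",
      path, paste(missing, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    spectrum_id = raw$spectrum_id,
    peptide = raw$peptide,
    protein = raw$protein,
    score = as.numeric(raw$score),
    identity_threshold = as.numeric(raw$identity_threshold),
    is_decoy = as.integer(raw$is_decoy) != 0L,
    sample = raw$sample
  )
  bad <- which(!is.finite(out$score) | !is.finite(out$identity_threshold) |
    is.na(out$is_decoy) | is.na(out$peptide) | !nzchar(out$peptide))
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed PSM row(s) in '%s': %s.",
      path, paste(head(bad, 5), collapse = ", ")
    ))
  }
  out
}

#' @rdname read_psm_table
#' @export
write_psm_table <- function(psms, path) {
  assert_psm_table(psms)
  out <- psms[psm_columns]
  out$is_decoy <- as.integer(out$is_decoy)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write GMT annotation files
#'
#' Standard GMT: one category per line, tab-separated as
#' `category<TAB>description<TAB>member1<TAB>member2...`. The reader returns
#' the long (tidy) form with one row per (category, protein).
#'
#' @param path File path.
#' @param annotations Tibble with columns `category`, `protein` and optional
#'   `description`.
#' @return `read_gmt()` returns a tibble `category`, `description`,
#'   `protein`; `write_gmt()` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read GMT file '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf(
      "GMT line(s) with fewer than 3 fields in '%s': %s.",
      path, paste(head(bad, 5), collapse = ", ")
    ))
  }
  purrr::map_dfr(fields, function(f) {
    tibble::tibble(
      category = f[1], description = f[2], protein = f[-(1:2)]
    )
  })
}

#' @rdname read_gmt
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(is.data.frame(annotations))
  if (!all(c("category", "protein") %in% names(annotations))) {
    abort("`annotations` needs columns `category` and `protein`.")
  }
  if (!"description" %in% names(annotations)) annotations$description <- "NA"
  lines <- annotations |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      line = paste(
        c(.data$category[1], .data$description[1], sort(unique(.data$protein))),
        collapse = "\t"
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category)
  writeLines(lines$line, path)
  invisible(path)
}

#' Read and write interaction edge lists
#'
#' Plain two-column TSV of accessions without a header line (one undirected
#' edge per row). [read_sif()] and [write_sif()] handle the three-column SIF
#' dialect (`from<TAB>interaction<TAB>to`) used by Cytoscape.
#'
#' @param path File path.
#' @param edges Tibble with columns `from`, `to`.
#' @param interaction Interaction type written into SIF, default `"pp"`.
#' @return Readers return a `from`/`to` tibble; writers return `path`
#'   invisibly.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read edge list '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed edge-list line(s) in '%s': %s.",
      path, paste(head(bad, 5), collapse = ", ")
    ))
  }
  tibble::tibble(
    from = vapply(fields, `[`, "", 1),
    to = vapply(fields, `[`, "", 2)
  )
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  writeLines(paste(edges$from, edges$to, sep = "\t"), path)
  invisible(path)
}

#' @rdname read_edge_list
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read SIF file '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed SIF line(s) in '%s': %s.",
      path, paste(head(bad, 5), collapse = ", ")
    ))
  }
  tibble::tibble(
    from = vapply(fields, `[`, "", 1),
    to = vapply(fields, `[`, "", 3)
  )
}

#' @rdname read_edge_list
#' @export
write_sif <- function(edges, path, interaction = "pp") {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  writeLines(paste(edges$from, interaction, edges$to, sep = "\t"), path)
  invisible(path)
}

#' Read and write protein-group tables
#'
#' Tab-delimited, one row per (protein, sample) with columns `protein`,
#' `sample`, `is_decoy` (0/1), `n_unique_peptides`, `n_spectra`.
#'
#' @param path File path.
#' @param groups Output of [infer_proteins()].
#' @return `read_protein_groups()` returns the groups tibble;
#'   `write_protein_groups()` returns `path` invisibly.
#' @export
read_protein_groups <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      protein = readr::col_character(),
      sample = readr::col_character(),
      is_decoy = readr::col_integer(),
      n_unique_peptides = readr::col_integer(),
      n_spectra = readr::col_integer()
    ),
    progress = FALSE
  ) |>
    dplyr::mutate(is_decoy = .data$is_decoy != 0L)
}

#' @rdname read_protein_groups
#' @export
write_protein_groups <- function(groups, path) {
  stopifnot(is.data.frame(groups))
  out <- groups
  out$is_decoy <- as.integer(out$is_decoy)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a differential table
#'
#' Fixed numeric formatting for diffable output: signed RSc with 4 decimal
#' places, logical flags as 0/1.
#'
#' @param records Output of [quantify_pair()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records |>
    dplyr::mutate(
      rsc_signed = sprintf("%.4f", .data$rsc_signed),
      partition = as.character(.data$partition),
      high_tier = as.integer(.data$high_tier)
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write an enrichment table
#'
#' p- and q-values in scientific notation with 6 significant digits, fold
#' with 4 decimal places.
#'
#' @param records Output of [enrich_set()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records |>
    dplyr::mutate(
      fold = sprintf("%.4f", .data$fold),
      p_value = sprintf("%.6e", .data$p_value),
      q_value = sprintf("%.6e", .data$q_value)
    )
  readr::write_tsv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}
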