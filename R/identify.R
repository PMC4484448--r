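#' Keep peptide-spectrum matches scoring above their identity threshold
#'
#' A PSM is significant when its search-engine ion score is strictly greater
#' than its own per-spectrum identity threshold. Row order is preserved and
#' the input is not modified.
#'
#' @param psms A PSM table (see [read_psm_table()] for the column contract).
#' @return The significant subset of `psms`, same columns.
#' @examples
#' psms <- tibble::tibble(
#'   spectrum_id = c("a", "b"), peptide = c("PEPTIDEK", "PEPTIDER"),
#'   protein = "P1", score = c(45.1, 45.0), identity_threshold = 45.0,
#'   is_decoy = FALSE, sample = "A"
#' )
#' filter_significant_psms(psms)
#' @export
filter_significant_psms <- function(psms) {
  assert_psm_table(psms)
  dplyr::filter(psms, .data$score > .data$identity_threshold)
}

# Distinct peptide sequences are compared case-insensitively after stripping
# bracketed modification notation, e.g. "PEPTM[+16]IDEK" == "peptmidek".
strip_modifications <- function(peptide) {
  toupper(gsub("\\[[^][]*\\]|\\([^()]*\\)", "", peptide))
}

#' Infer protein groups under a minimum-unique-peptide cut-off
#'
#' Groups significant PSMs by protein accession, counts distinct peptide
#' sequences (case-insensitive, modification notation stripped) over the
#' whole input, discards proteins with fewer than `min_unique_peptides`
#' distinct peptides, and tallies the significant spectra of every retained
#' protein per sample. A peptide shared by two accessions counts toward both
#' groups; no parsimony grouping is attempted.
#'
#' Pass one sample's PSMs for per-sample inference, or the pooled table for
#' study-wide inference (peptide uniqueness is then assessed study-wide).
#'
#' @param psms Score-filtered PSM table (see [filter_significant_psms()]).
#' @param min_unique_peptides Minimum number of distinct peptides per
#'   protein; default 2.
#' @return A tibble with one row per retained (protein, sample): `protein`,
#'   `sample`, `is_decoy`, `n_unique_peptides`, `n_spectra`.
#' @examples
#' psms <- tibble::tibble(
#'   spectrum_id = as.character(1:3), peptide = c("AAK", "CCK", "AAK"),
#'   protein = "P1", score = 50, identity_threshold = 40,
#'   is_decoy = FALSE, sample = "A"
#' )
#' infer_proteins(psms)
#' @export
infer_proteins <- function(psms, min_unique_peptides = 2L) {
  assert_psm_table(psms)
  if (length(min_unique_peptides) != 1 || min_unique_peptides < 1) {
    abort("`min_unique_peptides` must be a single integer >= 1.")
  }
  psms |>
    dplyr::mutate(.pep = strip_modifications(.data$peptide)) |>
    dplyr::group_by(.data$protein) |>
    dplyr::mutate(n_unique_peptides = dplyr::n_distinct(.data$.pep)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_unique_peptides >= min_unique_peptides) |>
    dplyr::count(.data$protein, .data$sample, .data$is_decoy,
      .data$n_unique_peptides,
      name = "n_spectra"
    ) |>
    dplyr::select(
      "protein", "sample", "is_decoy", "n_unique_peptides", "n_spectra"
    ) |>
    dplyr::arrange(.data$protein, .data$sample)
}

#' Estimate the protein-level target-decoy false discovery rate
#'
#' Counts distinct target and decoy protein accessions among the inferred
#' groups and reports `fdr = n_decoy / n_target`, the simple decoy/target
#' ratio. The alternative `(2 * n_decoy) / (n_target + n_decoy)` estimator is
#' available via `mode = "two_d"`.
#'
#' @param groups Output of [infer_proteins()].
#' @param mode `"d_over_t"` (default) or `"two_d"`.
#' @return A one-row tibble: `n_target_proteins`, `n_decoy_proteins`, `fdr`.
#' @examples
#' groups <- tibble::tibble(
#'   protein = c("P1", "P2", "DECOY_1"), sample = "A",
#'   is_decoy = c(FALSE, FALSE, TRUE), n_unique_peptides = 2, n_spectra = 4
#' )
#' estimate_fdr(groups)
#' @export
estimate_fdr <- function(groups, mode = c("d_over_t", "two_d")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(groups), all(c("protein", "is_decoy") %in% names(groups)))
  distinct <- dplyr::distinct(groups, .data$protein, .data$is_decoy)
  n_target <- sum(!distinct$is_decoy)
  n_decoy <- sum(distinct$is_decoy)
  if (n_target == 0) {
    abort("FDR is undefined: no target proteins were identified.")
  }
  fdr <- switch(mode,
    d_over_t = n_decoy / n_target,
    two_d = 2 * n_decoy / (n_target + n_decoy)
  )
  tibble::tibble(
    n_target_proteins = n_target,
    n_decoy_proteins = n_decoy,
    fdr = fdr
  )
}
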