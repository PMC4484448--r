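#' Signed ratio of normalized spectral counts (RSc)
#'
#' Relative protein abundance between a test and a reference sample from
#' significant spectral counts. With `s` the protein's significant spectra,
#' `T` the sample's total significant spectra, and pseudo-count `c`, the raw
#' ratio is
#'
#' \deqn{r = \frac{(s_{test}+c)\,(T_{ref}-s_{ref}+c)}
#'               {(s_{ref}+c)\,(T_{test}-s_{test}+c)}}
#'
#' so `r > 1` means enrichment in the test sample. When `r < 1` the negative
#' inverse `-1/r` is returned, so the result is symmetric fold-change-like:
#' `+k` means k-fold up in the test sample, `-k` k-fold up in the reference,
#' and no value falls in the open interval (-1, 1). The pseudo-count keeps
#' the ratio finite for proteins detected in only one sample.
#'
#' @param s_test,s_ref Significant spectral counts of the protein in the test
#'   and reference sample (non-negative integers).
#' @param t_test,t_ref Total significant spectral counts of each sample.
#' @param c Positive pseudo-count correction factor; default 1.25.
#' @return Numeric vector of signed RSc values.
#' @examples
#' compute_rsc(10, 5, 1000, 1000) # ~ +1.81, up in test
#' compute_rsc(0, 20, 500, 500) # ~ -17.7, up in reference
#' @export
compute_rsc <- function(s_test, s_ref, t_test, t_ref, c = 1.25) {
  if (length(c) != 1 || !is.finite(c) || c <= 0) {
    abort("`c` must be a single positive number.")
  }
  n <- max(length(s_test), length(s_ref), length(t_test), length(t_ref))
  s_test <- rep_len(as.numeric(s_test), n)
  s_ref <- rep_len(as.numeric(s_ref), n)
  t_test <- rep_len(as.numeric(t_test), n)
  t_ref <- rep_len(as.numeric(t_ref), n)
  if (any(s_test < 0 | s_ref < 0 | t_test < 0 | t_ref < 0, na.rm = TRUE)) {
    abort("Spectral counts must be non-negative.")
  }
  if (any(s_test > t_test | s_ref > t_ref, na.rm = TRUE)) {
    abort("Per-protein counts cannot exceed the sample totals (s > T).")
  }
  r <- ((s_test + c) * (t_ref - s_ref + c)) /
    ((s_ref + c) * (t_test - s_test + c))
  ifelse(r >= 1, r, -1 / r)
}

#' Classify signed RSc values against a fold cut-off
#'
#' Inclusive at the cut-off ("at least k-fold"): `higher` when
#' `rsc_signed >= fold_cutoff`, `lower` when `rsc_signed <= -fold_cutoff`,
#' else `unchanged`.
#'
#' @param rsc_signed Numeric vector of signed RSc values.
#' @param fold_cutoff Positive cut-off, default 2.
#' @return Factor with levels `higher`, `unchanged`, `lower`.
#' @examples
#' classify_rsc(c(29, 27, 20, 9, 6, 3, 1.5, -4))
#' @export
classify_rsc <- function(rsc_signed, fold_cutoff = 2) {
  if (fold_cutoff < 1) abort("`fold_cutoff` must be >= 1.")
  factor(
    dplyr::case_when(
      rsc_signed >= fold_cutoff ~ "higher",
      rsc_signed <= -fold_cutoff ~ "lower",
      TRUE ~ "unchanged"
    ),
    levels = c("higher", "unchanged", "lower")
  )
}

#' Differential quantitation of two samples by signed RSc
#'
#' Joins the protein groups of samples A (reference) and B (test), computes
#' each protein's signed RSc with per-sample totals taken as the sums of
#' significant spectra over retained target proteins, and assigns one of five
#' partitions: `unique_A` / `unique_B` for proteins detected in exactly one
#' sample (the absent sample contributes `s = 0`; the pseudo-count keeps the
#' ratio finite), and `common_higher_B` / `common_lower_B` /
#' `common_unchanged` for shared proteins against the inclusive
#' `fold_cutoff`. `high_tier` flags proteins strictly above
#' `high_tier_cutoff` ("more than 15-fold").
#'
#' Decoy groups (rows with `is_decoy = TRUE`) are excluded before totals are
#' computed.
#'
#' @param groups_a,groups_b Protein groups of the reference (A) and test (B)
#'   sample, as returned by [infer_proteins()]; only `protein` and
#'   `n_spectra` are required.
#' @param c Pseudo-count correction factor, default 1.25.
#' @param fold_cutoff Inclusive fold cut-off for the higher/lower partitions,
#'   default 2.
#' @param high_tier_cutoff Strict cut-off for the high tier, default 15.
#' @return A tibble with one row per protein in the union: `protein`, `s_a`,
#'   `s_b`, `t_a`, `t_b`, `rsc_signed`, `partition` (factor over the five
#'   labels), `high_tier`.
#' @examples
#' a <- tibble::tibble(protein = c("P1", "P3"), n_spectra = c(10, 4))
#' b <- tibble::tibble(protein = c("P1", "P2", "P3"), n_spectra = c(40, 6, 4))
#' quantify_pair(a, b)
#' @export
quantify_pair <- function(groups_a, groups_b, c = 1.25, fold_cutoff = 2,
                          high_tier_cutoff = 15) {
  if (fold_cutoff < 1 || high_tier_cutoff < fold_cutoff) {
    abort("Need `fold_cutoff` >= 1 and `high_tier_cutoff` >= `fold_cutoff`.")
  }
  tally <- function(groups, arg) {
    stopifnot(is.data.frame(groups))
    if (!all(c("protein", "n_spectra") %in% names(groups))) {
      abort(sprintf("`%s` needs columns `protein` and `n_spectra`.", arg))
    }
    if ("is_decoy" %in% names(groups)) {
      groups <- dplyr::filter(groups, !.data$is_decoy)
    }
    groups |>
      dplyr::group_by(.data$protein) |>
      dplyr::summarise(s = sum(.data$n_spectra), .groups = "drop")
  }
  a <- tally(groups_a, "groups_a")
  b <- tally(groups_b, "groups_b")
  if (nrow(a) == 0 && nrow(b) == 0) {
    return(tibble::tibble(
      protein = character(), s_a = integer(), s_b = integer(),
      t_a = integer(), t_b = integer(), rsc_signed = numeric(),
      partition = factor(character(), levels = partition_levels),
      high_tier = logical()
    ))
  }
  t_a <- sum(a$s)
  t_b <- sum(b$s)
  if (t_a == 0 || t_b == 0) {
    abort("A sample has zero total significant spectra; RSc is undefined.")
  }
  merged <- dplyr::full_join(
    dplyr::rename(a, s_a = "s"), dplyr::rename(b, s_b = "s"),
    by = "protein"
  ) |>
    dplyr::mutate(
      s_a = dplyr::coalesce(.data$s_a, 0L),
      s_b = dplyr::coalesce(.data$s_b, 0L)
    ) |>
    dplyr::filter(.data$s_a + .data$s_b > 0)

  merged |>
    dplyr::mutate(
      t_a = t_a,
      t_b = t_b,
      rsc_signed = compute_rsc(.data$s_b, .data$s_a, t_b, t_a, c = c),
      partition = factor(
        dplyr::case_when(
          .data$s_b == 0 ~ "unique_A",
          .data$s_a == 0 ~ "unique_B",
          .data$rsc_signed >= fold_cutoff ~ "common_higher_B",
          .data$rsc_signed <= -fold_cutoff ~ "common_lower_B",
          TRUE ~ "common_unchanged"
        ),
        levels = partition_levels
      ),
      high_tier = .data$rsc_signed > high_tier_cutoff
    ) |>
    dplyr::arrange(.data$protein)
}

#' Summarise a differential partition
#'
#' Counts the five partitions, the union total, and the "at least
#' `fold_cutoff`-fold increase in sample B" set, defined as the unique-to-B
#' proteins plus the common proteins of higher abundance in B.
#'
#' @param records Output of [quantify_pair()] (needs a `partition` column).
#' @return A one-row tibble: `n_unique_a`, `n_common_higher_b`,
#'   `n_common_unchanged`, `n_common_lower_b`, `n_unique_b`, `n_common`,
#'   `n_total`, `n_increased_b`.
#' @examples
#' summarize_partition(quantify_pair(
#'   tibble::tibble(protein = "P1", n_spectra = 10),
#'   tibble::tibble(protein = c("P1", "P2"), n_spectra = c(30, 5))
#' ))
#' @export
summarize_partition <- function(records) {
  stopifnot(is.data.frame(records), "partition" %in% names(records))
  part <- factor(records$partition, levels = partition_levels)
  counts <- table(part)
  tibble::tibble(
    n_unique_a = as.integer(counts[["unique_A"]]),
    n_common_higher_b = as.integer(counts[["common_higher_B"]]),
    n_common_unchanged = as.integer(counts[["common_unchanged"]]),
    n_common_lower_b = as.integer(counts[["common_lower_B"]]),
    n_unique_b = as.integer(counts[["unique_B"]]),
    n_common = n_common_higher_b + n_common_unchanged + n_common_lower_b,
    n_total = nrow(records),
    n_increased_b = n_unique_b + n_common_higher_b
  )
}
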