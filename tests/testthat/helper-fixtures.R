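# Small bundles used across the unit tests; the study-scale defaults are
# exercised in test-acceptance.R.

tiny_config <- function(seed = 1L, ...) {
  simulation_config(
    n_proteins = 120L, total_spectra_per_sample = 600L,
    module_size = 10L, seed = seed, ...
  )
}

make_psms <- function(score, threshold = 40, peptide = NULL, protein = "P1",
                      sample = "A", is_decoy = FALSE) {
  n <- max(length(score), length(peptide %||% ""), length(protein))
  tibble::tibble(
    spectrum_id = sprintf("spec%03d", seq_len(n)),
    peptide = rep_len(peptide %||% sprintf("PEPTIDE%03dK", seq_len(n)), n),
    protein = rep_len(protein, n),
    score = rep_len(score, n),
    identity_threshold = rep_len(threshold, n),
    is_decoy = rep_len(is_decoy, n),
    sample = rep_len(sample, n)
  )
}

`%||%` <- rlang::`%||%`

# Independent evaluation of the spectral-count ratio as printed: the raw
# ratio term by term, then the negative-inverse rule, scalar arithmetic only.
rsc_oracle <- function(s_test, s_ref, t_test, t_ref, c = 1.25) {
  stopifnot(length(s_test) == 1)
  num <- (s_test + c) * (t_ref - s_ref + c)
  den <- (s_ref + c) * (t_test - s_test + c)
  r <- num / den
  if (r < 1) -den / num else r
}

# Exhaustive hypergeometric tails: enumerate every n-subset of N items of
# which the first K are category members, and count overlap sizes.
hyper_enum <- function(k, n, K, N, direction) {
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  if (direction == "enriched") mean(overlap >= k) else mean(overlap <= k)
}
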