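test_that("significance filtering is strictly above the identity threshold", {
  psms <- make_psms(score = c(45.1, 45.0, 44.9), threshold = 45.0)
  kept <- filter_significant_psms(psms)
  expect_equal(kept$score, 45.1)

  empty <- psms[0, ]
  expect_equal(nrow(filter_significant_psms(empty)), 0)

  # idempotence and order preservation
  cfg <- tiny_config(seed = 2)
  sim <- simulate_psm_table(generate_truth(cfg), cfg)
  once <- filter_significant_psms(sim)
  expect_identical(filter_significant_psms(once), once)
  expect_identical(once$spectrum_id, sim$spectrum_id[sim$score > sim$identity_threshold])
})

test_that("malformed PSM tables are rejected with informative errors", {
  psms <- make_psms(score = 50)
  expect_error(filter_significant_psms(psms[, -4]), "score")
  bad <- psms
  bad$score <- NaN
  expect_error(filter_significant_psms(bad), "non-finite")
  bad2 <- psms
  bad2$peptide <- ""
  expect_error(filter_significant_psms(bad2), "empty peptide")
})

test_that("protein inference applies the two-unique-peptide rule with set semantics", {
  psms <- dplyr::bind_rows(
    make_psms(score = 50, peptide = c("PEPTIDEA", "PEPTIDEB"), protein = "KEEP"),
    make_psms(score = 50, peptide = rep("ONLYPEP", 5), protein = "ONEPEP"),
    make_psms(score = 50, peptide = c("AAK", "AAK"), protein = "DUP"),
    make_psms(score = 50, peptide = c("SEQM[+16]K", "seqmk"), protein = "MODS")
  )
  groups <- infer_proteins(psms)
  expect_setequal(groups$protein, "KEEP")
  expect_equal(groups$n_unique_peptides, 2)
  expect_equal(groups$n_spectra, 2)

  # modification stripping and case folding collapse to one sequence
  expect_false("MODS" %in% groups$protein)
  # but they count as one protein at min_unique_peptides = 1
  expect_true("MODS" %in% infer_proteins(psms, min_unique_peptides = 1)$protein)

  expect_error(infer_proteins(psms, min_unique_peptides = 0), "must be")
})

test_that("spectra tallies cover all significant PSMs of retained proteins", {
  cfg <- tiny_config(seed = 6)
  sig <- filter_significant_psms(simulate_psm_table(generate_truth(cfg), cfg))
  groups <- infer_proteins(sig)
  tallied <- sig |>
    dplyr::filter(protein %in% groups$protein) |>
    dplyr::count(protein, sample, name = "expected")
  merged <- dplyr::inner_join(groups, tallied, by = c("protein", "sample"))
  expect_equal(nrow(merged), nrow(groups))
  expect_equal(merged$n_spectra, merged$expected)
})

test_that("raising the unique-peptide cut-off never adds proteins", {
  cfg <- tiny_config(seed = 4)
  sig <- filter_significant_psms(simulate_psm_table(generate_truth(cfg), cfg))
  sizes <- vapply(
    1:5,
    function(m) length(unique(infer_proteins(sig, m)$protein)),
    integer(1)
  )
  expect_true(all(diff(sizes) <= 0))
  # and every stricter set is nested in the looser one
  expect_true(all(
    unique(infer_proteins(sig, 3)$protein) %in% unique(infer_proteins(sig, 2)$protein)
  ))
})

test_that("the target-decoy FDR estimator matches direct arithmetic", {
  groups <- tibble::tibble(
    protein = c(sprintf("T%03d", 1:990), sprintf("D%03d", 1:9)),
    sample = "A",
    is_decoy = rep(c(FALSE, TRUE), c(990, 9)),
    n_unique_peptides = 2L,
    n_spectra = 3L
  )
  est <- estimate_fdr(groups)
  expect_equal(est$fdr, 9 / 990, tolerance = 1e-12)
  expect_equal(est$n_target_proteins, 990)
  expect_equal(est$n_decoy_proteins, 9)
  expect_equal(estimate_fdr(groups, mode = "two_d")$fdr, 18 / 999, tolerance = 1e-12)

  # a protein listed in both samples is still one identification
  doubled <- dplyr::bind_rows(groups, dplyr::mutate(groups, sample = "B"))
  expect_equal(estimate_fdr(doubled)$n_target_proteins, 990)

  no_decoys <- dplyr::filter(groups, !is_decoy)
  expect_equal(estimate_fdr(no_decoys)$fdr, 0)
  expect_error(estimate_fdr(dplyr::filter(groups, is_decoy)), "undefined")
})
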