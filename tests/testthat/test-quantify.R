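test_that("signed RSc reproduces direct evaluation of the count-ratio formula", {
  expect_equal(compute_rsc(5, 5, 1000, 1000), 1.0)
  expect_equal(
    compute_rsc(10, 5, 1000, 1000),
    (11.25 * 996.25) / (6.25 * 991.25),
    tolerance = 1e-12
  )
  # negative-inverse branch for a protein absent from the test sample
  expect_equal(
    compute_rsc(0, 20, 500, 500),
    -(21.25 * 501.25) / (1.25 * 481.25),
    tolerance = 1e-12
  )
  # pseudo-count keeps single-sample proteins finite
  expect_true(is.finite(compute_rsc(30, 0, 1000, 1000)))
})

test_that("RSc rejects impossible counts and pseudo-counts", {
  expect_error(compute_rsc(10, 5, 8, 1000), "exceed")
  expect_error(compute_rsc(10, 5, 1000, 4), "exceed")
  expect_error(compute_rsc(-1, 5, 1000, 1000), "non-negative")
  expect_error(compute_rsc(10, 5, 1000, 1000, c = 0), "positive")
  expect_error(compute_rsc(10, 5, 1000, 1000, c = -1.25), "positive")
})

test_that("RSc is antisymmetric, gapped away from (-1, 1), and monotone", {
  set.seed(101)
  t_test <- sample(100:5000, 500, replace = TRUE)
  t_ref <- sample(100:5000, 500, replace = TRUE)
  s_test <- vapply(t_test, function(t) sample(0:min(t, 80), 1), integer(1))
  s_ref <- vapply(t_ref, function(t) sample(0:min(t, 80), 1), integer(1))

  fwd <- compute_rsc(s_test, s_ref, t_test, t_ref)
  rev <- compute_rsc(s_ref, s_test, t_ref, t_test)
  expect_true(all(abs(fwd) >= 1))
  off_unity <- abs(fwd) > 1 + 1e-12
  expect_equal(fwd[off_unity], -rev[off_unity], tolerance = 1e-9)

  # element-wise agreement with the independent scalar oracle
  for (i in sample(500, 50)) {
    expect_equal(
      fwd[i], rsc_oracle(s_test[i], s_ref[i], t_test[i], t_ref[i]),
      tolerance = 1e-9
    )
  }

  # monotone in s_test (up) and s_ref (down) at fixed totals
  grid <- compute_rsc(0:50, 25, 1000, 1000)
  expect_true(all(diff(grid) > 0))
  grid2 <- compute_rsc(25, 0:50, 1000, 1000)
  expect_true(all(diff(grid2) < 0))
})

test_that("fold-change classification is inclusive at the cut-off", {
  folds <- c(29, 27, 20, 9, 6, 3)
  expect_true(all(classify_rsc(folds) == "higher"))
  expect_equal(
    as.character(classify_rsc(c(2, 1.999, 1, -1.5, -2, -2.01))),
    c("higher", "unchanged", "unchanged", "unchanged", "lower", "lower")
  )
})

test_that("pairwise quantitation partitions a toy table as hand-computed", {
  a <- tibble::tibble(protein = c("P1", "P2", "P3"), n_spectra = c(10L, 0L, 4L))
  b <- tibble::tibble(protein = c("P1", "P2", "P3"), n_spectra = c(40L, 6L, 4L))
  d <- quantify_pair(a, b)
  expect_equal(d$t_a, rep(14, 3))
  expect_equal(d$t_b, rep(50, 3))

  p1 <- d[d$protein == "P1", ]
  expect_equal(p1$rsc_signed, (41.25 * 5.25) / (11.25 * 11.25), tolerance = 1e-12)
  expect_equal(as.character(p1$partition), "common_unchanged")

  p2 <- d[d$protein == "P2", ]
  expect_equal(as.character(p2$partition), "unique_B")

  p3 <- d[d$protein == "P3", ]
  expect_equal(p3$rsc_signed, -4.2, tolerance = 1e-12)
  expect_equal(as.character(p3$partition), "common_lower_B")

  expect_false(any(d$high_tier))
})

test_that("unique/common partitions are exhaustive, disjoint and complete", {
  cfg <- tiny_config(seed = 12)
  sig <- filter_significant_psms(simulate_psm_table(generate_truth(cfg), cfg))
  d <- quantify_pair(
    infer_proteins(dplyr::filter(sig, sample == cfg$samples[1])),
    infer_proteins(dplyr::filter(sig, sample == cfg$samples[2]))
  )
  expect_false(any(is.na(d$partition)))
  expect_equal(anyDuplicated(d$protein), 0)
  expect_true(all(abs(d$rsc_signed) >= 1))
  expect_true(all(d$s_a <= d$t_a & d$s_b <= d$t_b))
  # unique labels iff absent from exactly one sample
  expect_equal(d$partition == "unique_A", d$s_b == 0)
  expect_equal(d$partition == "unique_B", d$s_a == 0)

  s <- summarize_partition(d)
  expect_equal(
    s$n_unique_a + s$n_common + s$n_unique_b, s$n_total
  )
  expect_equal(
    s$n_common,
    s$n_common_higher_b + s$n_common_unchanged + s$n_common_lower_b
  )
  expect_equal(s$n_increased_b, s$n_unique_b + s$n_common_higher_b)
  expect_equal(s$n_total, nrow(d))

  # with fold_cutoff = 1 only exact unity stays unchanged
  d1 <- quantify_pair(
    infer_proteins(dplyr::filter(sig, sample == cfg$samples[1])),
    infer_proteins(dplyr::filter(sig, sample == cfg$samples[2])),
    fold_cutoff = 1
  )
  unchanged <- dplyr::filter(d1, partition == "common_unchanged")
  expect_true(all(unchanged$rsc_signed == 1))
})

test_that("degenerate quantitation inputs behave per contract", {
  empty <- tibble::tibble(protein = character(), n_spectra = integer())
  expect_equal(nrow(quantify_pair(empty, empty)), 0)
  expect_equal(summarize_partition(quantify_pair(empty, empty))$n_total, 0)

  a <- tibble::tibble(protein = "P1", n_spectra = 0L)
  b <- tibble::tibble(protein = "P1", n_spectra = 5L)
  expect_error(quantify_pair(a, b), "zero total")
  expect_error(quantify_pair(a, a), "zero total")

  # decoy groups are excluded from totals and the union
  withd <- tibble::tibble(
    protein = c("P1", "DECOY_1"), n_spectra = c(10L, 99L),
    is_decoy = c(FALSE, TRUE)
  )
  d <- quantify_pair(withd, dplyr::mutate(withd, n_spectra = c(20L, 50L)))
  expect_equal(d$protein, "P1")
  expect_equal(d$t_a, 10)
  expect_equal(d$t_b, 20)
})
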