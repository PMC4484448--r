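test_that("configuration validation rejects impossible study designs", {
  expect_error(simulation_config(frac_differential = 1.2), "fraction")
  expect_error(simulation_config(decoy_fraction = -0.1), "fraction")
  expect_error(simulation_config(leakage_fraction_per_sample = c(0.5, 1.5)), "fraction")
  expect_error(simulation_config(fold_range = c(0.5, 2)), "fold_range")
  expect_error(simulation_config(fold_range = c(4, 2)), "fold_range")
  expect_error(
    simulation_config(n_proteins = 10, module_size = 11),
    "module_size"
  )
  expect_error(simulation_config(total_spectra_per_sample = 0), "positive")
})

test_that("truth generation is deterministic and plants the configured design", {
  cfg <- tiny_config(seed = 7)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  expect_identical(
    generate_truth(tiny_config(seed = 8)),
    generate_truth(tiny_config(seed = 8))
  )
  expect_false(identical(t1, generate_truth(tiny_config(seed = 8))))

  # exact differential count forced by the rounding rule
  cfg2 <- simulation_config(n_proteins = 1000, frac_differential = 0.2, seed = 1)
  expect_equal(sum(abs(generate_truth(cfg2)$fold) > 1), 200)

  # null planting
  null_truth <- generate_truth(tiny_config(seed = 3, frac_differential = 0))
  expect_true(all(null_truth$fold == 1))

  # module members share one category and are up in sample B
  mod <- dplyr::filter(t1, module)
  expect_equal(nrow(mod), cfg$module_size)
  expect_length(unique(mod$category), 1)
  expect_true(all(mod$fold > 1))
  expect_true(all(mod$n_peptides >= 2))

  # contaminants carry intracellular nucleic-acid-binding annotations
  cont <- dplyr::filter(t1, contaminant)
  expect_true(all(cont$category %in% c("DNA binding", "RNA binding")))
})

test_that("simulated PSM tables honour depth, decoys and determinism", {
  cfg <- tiny_config(seed = 5)
  truth <- generate_truth(cfg)
  psms <- simulate_psm_table(truth, cfg)
  expect_identical(psms, simulate_psm_table(truth, cfg))

  by_sample <- dplyr::count(dplyr::filter(psms, !is_decoy), sample)
  expect_setequal(by_sample$sample, cfg$samples)
  expect_true(all(by_sample$n == cfg$total_spectra_per_sample))

  n_decoy <- sum(psms$is_decoy)
  expect_equal(n_decoy, 2 * round(cfg$decoy_fraction * cfg$total_spectra_per_sample))

  no_decoy <- tiny_config(seed = 5, decoy_fraction = 0)
  psms0 <- simulate_psm_table(generate_truth(no_decoy), no_decoy)
  expect_false(any(psms0$is_decoy))
})

test_that("a median-abundance protein with planted fold 8 gains spectra in sample B", {
  hits <- vapply(1:100, function(s) {
    cfg <- simulation_config(
      n_proteins = 200, total_spectra_per_sample = 2000,
      fold_range = c(8, 8), module_size = 0, seed = 100 + s
    )
    truth <- generate_truth(cfg)
    up <- dplyr::filter(truth, fold >= 8)
    target <- up$protein[which.min(abs(up$baseline - median(truth$baseline)))]
    counts <- simulate_psm_table(truth, cfg) |>
      dplyr::filter(protein == target) |>
      dplyr::count(sample) |>
      tidyr::pivot_wider(names_from = sample, values_from = n, values_fill = 0L)
    for (lab in cfg$samples) if (!lab %in% names(counts)) counts[[lab]] <- 0L
    counts[[cfg$samples[2]]] > counts[[cfg$samples[1]]]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("leakage reassigns spectra to contaminant proteins at the configured rate", {
  cfg <- simulation_config(
    n_proteins = 300, total_spectra_per_sample = 5000, seed = 9
  )
  truth <- generate_truth(cfg)
  psms <- simulate_psm_table(truth, cfg)
  cont <- truth$protein[truth$contaminant]
  for (i in 1:2) {
    n_cont <- sum(psms$protein %in% cont & psms$sample == cfg$samples[i])
    expect_equal(
      n_cont,
      round(cfg$leakage_fraction_per_sample[i] * cfg$total_spectra_per_sample)
    )
  }
})

test_that("the fixture bundle round-trips and matches the planted design", {
  cfg <- tiny_config(seed = 11)
  truth <- generate_truth(cfg)
  psms <- simulate_psm_table(truth, cfg)
  dir <- withr::local_tempdir()
  files <- write_fixture_bundle(truth, psms, dir)

  back <- dplyr::bind_rows(
    read_psm_table(files[["psm_SH-SY5Y-like"]]),
    read_psm_table(files[["psm_SK-N-BE2-like"]])
  )
  expect_equal(
    dplyr::arrange(back, spectrum_id, sample),
    dplyr::arrange(psms, spectrum_id, sample)
  )

  gmt <- read_gmt(files[["gmt"]])
  expect_equal(length(unique(gmt$category)), length(unique(truth$category)))
  expect_setequal(gmt$protein, truth$protein)

  # the planted module is densely wired by construction
  edges <- read_edge_list(files[["edges"]])
  mod <- truth$protein[truth$module]
  internal <- sum(edges$from %in% mod & edges$to %in% mod)
  m <- length(mod)
  expect_gte(internal, ceiling(0.6 * m * (m - 1) / 2))

  # byte-identical regeneration under the same configuration
  dir2 <- withr::local_tempdir()
  files2 <- write_fixture_bundle(truth, psms, dir2)
  for (key in names(files)) {
    expect_identical(readLines(files[[key]]), readLines(files2[[key]]))
  }
})

test_that("a null experiment yields a signed RSc distribution symmetric about one", {
  null_medians <- function(depth, seeds) {
    t(vapply(seeds, function(s) {
      cfg <- simulation_config(
        n_proteins = 300, frac_differential = 0, module_size = 0,
        total_spectra_per_sample = depth, decoy_fraction = 0, seed = s
      )
      truth <- generate_truth(cfg)
      sig <- filter_significant_psms(simulate_psm_table(truth, cfg))
      d <- quantify_pair(
        infer_proteins(dplyr::filter(sig, sample == cfg$samples[1])),
        infer_proteins(dplyr::filter(sig, sample == cfg$samples[2]))
      )
      common <- dplyr::filter(d, s_a > 0, s_b > 0)
      c(median(abs(common$rsc_signed)), mean(common$rsc_signed > 0))
    }, numeric(2)))
  }
  deep <- null_medians(10000, 401:450)
  # signs balanced about the null value 1
  expect_lt(abs(mean(deep[, 2]) - 0.5), 0.05)
  # median |RSc| approaches 1 as sampling depth grows
  shallow <- null_medians(1000, 401:425)
  expect_lt(mean(deep[, 1]), mean(shallow[, 1]))
  expect_lt(mean(deep[, 1]), 1.35)
  expect_gte(mean(deep[, 1]), 1)
})
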