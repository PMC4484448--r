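#' Configure a synthetic two-condition secretome experiment
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' generator emulates a label-free spectral-counting comparison of two
#' secretomes: sample A plays the part of a less aggressive line
#' ("SH-SY5Y-like") and sample B an N-Myc-amplified, more aggressive line
#' ("SK-N-BE2-like"). A fraction of proteins carries a planted fold change,
#' one densely interacting protease-like module is co-enriched in sample B,
#' decoy spectra emulate the target-decoy search, and a small fraction of
#' spectra per sample is reassigned to intracellular contaminant proteins,
#' mimicking cell-death-derived leakage into conditioned media.
#'
#' @param n_proteins Number of target proteins in the simulated secretome.
#' @param frac_differential Fraction of proteins given a planted fold change
#'   (`|fold| > 1`); exactly `round(frac_differential * n_proteins)` proteins
#'   are differential.
#' @param fold_range Length-2 numeric, low and high bound of planted fold
#'   magnitudes; `fold_range[1] >= 1`.
#' @param total_spectra_per_sample Target number of significant-scale spectra
#'   drawn per sample (the depth analogue of one LC-MS/MS run).
#' @param decoy_fraction Decoy spectra drawn per sample, as a fraction of
#'   `total_spectra_per_sample`; decoys are extra rows on top of the target
#'   depth.
#' @param leakage_fraction_per_sample Length-2 numeric, fraction of each
#'   sample's spectra reassigned to contaminant (intracellular) proteins.
#'   The defaults (8.5% and 7.8%) mirror a realistic differential in
#'   cell death between the two cultures.
#' @param module_size Size of the planted co-enriched protease-like module;
#'   its members share one annotation category and are up in sample B.
#' @param seed Integer seed; every random draw downstream is a deterministic
#'   function of the configuration including this seed.
#' @param samples Length-2 character, labels for samples A and B.
#' @param frac_single_peptide Fraction of proteins deliberately given a
#'   one-peptide inventory so the two-unique-peptide inference filter is
#'   exercised.
#' @param frac_contaminant Fraction of proteins flagged as intracellular
#'   contaminants; they receive spectra only through leakage and carry
#'   "DNA binding"/"RNA binding" annotations.
#' @param target_protein_fdr Protein-level false discovery rate the decoy
#'   score model is calibrated to; the decoy score shift is derived so the
#'   expected rate of decoy protein groups among identifications equals this
#'   value (see [simulate_psm_table()]).
#' @param decoy_psms_per_protein Decoy spectra grouped per decoy accession,
#'   each with a distinct peptide.
#' @param score_location,score_spread Mean and standard deviation of the
#'   per-spectrum identity threshold (Mascot-like score scale).
#' @param target_score_margin,score_sd Mean margin of target scores above
#'   their identity threshold, and the score noise standard deviation shared
#'   by targets and decoys.
#'
#' @return A list of class `speccount_config`.
#' @examples
#' cfg <- simulation_config(n_proteins = 200, seed = 7)
#' cfg$fold_range
#' @seealso [generate_truth()], [simulate_psm_table()], [write_fixture_bundle()]
#' @export
simulation_config <- function(n_proteins = 900L,
                              frac_differential = 0.2,
                              fold_range = c(2, 30),
                              total_spectra_per_sample = 2000L,
                              decoy_fraction = 0.1,
                              leakage_fraction_per_sample = c(0.085, 0.078),
                              module_size = 20L,
                              seed = 1L,
                              samples = c("SH-SY5Y-like", "SK-N-BE2-like"),
                              frac_single_peptide = 0.1,
                              frac_contaminant = 0.08,
                              target_protein_fdr = 0.005,
                              decoy_psms_per_protein = 3L,
                              score_location = 40,
                              score_spread = 2,
                              target_score_margin = 12,
                              score_sd = 8) {
  n_proteins <- as.integer(n_proteins)
  module_size <- as.integer(module_size)
  total_spectra_per_sample <- as.integer(total_spectra_per_sample)
  if (n_proteins < 1) abort("`n_proteins` must be a positive integer.")
  if (total_spectra_per_sample < 1) {
    abort("`total_spectra_per_sample` must be a positive integer.")
  }
  fracs <- c(
    frac_differential = frac_differential,
    decoy_fraction = decoy_fraction,
    frac_single_peptide = frac_single_peptide,
    frac_contaminant = frac_contaminant,
    leakage_A = leakage_fraction_per_sample[1],
    leakage_B = leakage_fraction_per_sample[2]
  )
  bad <- fracs < 0 | fracs > 1 | !is.finite(fracs)
  if (length(leakage_fraction_per_sample) != 2 || any(bad)) {
    abort(sprintf(
      "All fractions must lie in [0, 1]; offending: %s.",
      paste(names(fracs)[bad], collapse = ", ")
    ))
  }
  if (length(fold_range) != 2 || fold_range[1] < 1 || fold_range[2] < fold_range[1]) {
    abort("`fold_range` must be c(low, high) with 1 <= low <= high.")
  }
  if (module_size > n_proteins) {
    abort("`module_size` must not exceed `n_proteins`.")
  }
  if (length(samples) != 2 || anyDuplicated(samples)) {
    abort("`samples` must be two distinct labels.")
  }
  structure(
    list(
      n_proteins = n_proteins,
      frac_differential = frac_differential,
      fold_range = as.numeric(fold_range),
      total_spectra_per_sample = total_spectra_per_sample,
      decoy_fraction = decoy_fraction,
      leakage_fraction_per_sample = as.numeric(leakage_fraction_per_sample),
      module_size = module_size,
      seed = as.integer(seed),
      samples = as.character(samples),
      frac_single_peptide = frac_single_peptide,
      frac_contaminant = frac_contaminant,
      target_protein_fdr = target_protein_fdr,
      decoy_psms_per_protein = as.integer(decoy_psms_per_protein),
      score_location = score_location,
      score_spread = score_spread,
      target_score_margin = target_score_margin,
      score_sd = score_sd
    ),
    class = "speccount_config"
  )
}

# Annotation vocabulary used by the generator. The first entry is reserved for
# the planted module, the next two for intracellular contaminants.
module_category <- "cysteine-type peptidase activity"
contaminant_categories <- c("DNA binding", "RNA binding")
background_categories <- c(
  "cell adhesion", "serine-type peptidase activity", "receptor binding",
  "ECM structural constituent", "transporter activity",
  "growth factor activity", "chaperone activity",
  "protease inhibitor activity", "calcium ion binding",
  "glycosyltransferase activity", "cytoskeletal protein binding",
  "oxidoreductase activity", "lipid binding", "enzyme regulator activity",
  "cell-cell signaling"
)

#' Generate the ground truth of a synthetic secretome experiment
#'
#' Draws per-protein baseline abundances, plants signed fold changes for a
#' fixed number of differential proteins, places a co-enriched module (all
#' members up in sample B, sharing one annotation category), flags
#' intracellular contaminant proteins, and assigns every protein an
#' annotation category and a peptide inventory size.
#'
#' The signed fold convention matches the downstream RSc sign convention:
#' `fold >= 1` means up in sample B, `fold <= -1` up in sample A, and
#' `fold == 1` means no change.
#'
#' @param config A [simulation_config()].
#' @return A tibble of class `speccount_truth` with one row per protein:
#'   `protein`, `baseline` (relative abundance), `fold` (signed), `module`,
#'   `contaminant` (logicals), `category`, `n_peptides`. The configuration is
#'   attached as attribute `config`.
#' @examples
#' truth <- generate_truth(simulation_config(n_proteins = 100, seed = 1))
#' sum(abs(truth$fold) > 1)
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "speccount_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  protein <- sprintf("PROT%05d", seq_len(n))
  baseline <- rlnorm(n, meanlog = 0, sdlog = 1)

  # Module members are drawn from the upper half of the abundance range:
  # secreted proteases of the aggressive phenotype are well-detected proteins.
  eligible <- which(baseline >= median(baseline))
  module_idx <- sample(eligible, min(config$module_size, length(eligible)))
  module <- seq_len(n) %in% module_idx

  contaminant <- rep(FALSE, n)
  n_cont <- round(config$frac_contaminant * n)
  cont_pool <- setdiff(seq_len(n), module_idx)
  if (n_cont > 0) contaminant[sample(cont_pool, min(n_cont, length(cont_pool)))] <- TRUE

  n_diff <- round(config$frac_differential * n)
  fold <- rep(1, n)
  # Module members claim the differential budget first and are up in B with
  # folds from the top half of the configured range.
  mod_diff <- head(module_idx, n_diff)
  if (length(mod_diff) > 0) {
    lo <- max(config$fold_range[1], config$fold_range[2] / 2)
    fold[mod_diff] <- runif(length(mod_diff), lo, config$fold_range[2])
  }
  n_rest <- n_diff - length(mod_diff)
  if (n_rest > 0) {
    rest_pool <- setdiff(which(!module & !contaminant), mod_diff)
    rest <- sample(rest_pool, n_rest)
    mag <- runif(n_rest, config$fold_range[1], config$fold_range[2])
    sign_up <- runif(n_rest) < 0.5
    fold[rest] <- ifelse(sign_up, mag, -mag)
  }

  category <- sample(background_categories, n, replace = TRUE)
  category[contaminant] <- sample(contaminant_categories, sum(contaminant),
    replace = TRUE
  )
  category[module] <- module_category

  single <- runif(n) < config$frac_single_peptide
  single[module] <- FALSE # the planted module must survive inference
  n_peptides <- ifelse(single, 1L, 2L + rpois(n, 3))

  out <- tibble::tibble(
    protein = protein, baseline = baseline, fold = fold,
    module = module, contaminant = contaminant,
    category = category, n_peptides = as.integer(n_peptides)
  )
  attr(out, "config") <- config
  class(out) <- c("speccount_truth", class(out))
  out
}

# Per-sample expected spectra weights, mirroring simulate_psm_table():
# contaminants receive spectra only through the leakage channel.
sample_weights <- function(truth, which_sample) {
  w <- truth$baseline
  if (which_sample == 2L) {
    w <- w * ifelse(truth$fold >= 1, truth$fold, 1)
  } else {
    w <- w * ifelse(truth$fold <= -1, -truth$fold, 1)
  }
  w[truth$contaminant] <- 0
  w
}

# Expected number of identified target proteins (pooled over both samples),
# under a Poisson approximation of per-protein spectral counts and the
# two-unique-peptide rule. Used to calibrate the decoy score shift.
expected_identified_targets <- function(truth, config, min_unique_peptides = 2L) {
  depth <- config$total_spectra_per_sample
  lam <- rep(0, nrow(truth))
  for (s in 1:2) {
    leak <- config$leakage_fraction_per_sample[s]
    n_leak <- round(leak * depth)
    w <- sample_weights(truth, s)
    lam <- lam + (depth - n_leak) * w / sum(w)
    if (n_leak > 0 && any(truth$contaminant)) {
      b <- ifelse(truth$contaminant, truth$baseline, 0)
      lam <- lam + n_leak * b / sum(b)
    }
  }
  p_sig <- pnorm(config$target_score_margin / config$score_sd)
  mu <- lam * p_sig
  m <- truth$n_peptides
  # P(>= 2 significant PSMs hitting >= 2 distinct peptides), with peptides
  # drawn uniformly from an inventory of m: P(all k draws same peptide) =
  # m^(1-k), summed against the Poisson weights in closed form.
  s_same <- ifelse(m > 1, m * exp(-mu) * (exp(mu / m) - 1 - mu / m), 0)
  p_ident <- ifelse(m >= min_unique_peptides,
    pmax(0, 1 - exp(-mu) * (1 + mu) - s_same),
    0
  )
  sum(p_ident)
}

# Significance probability p for one decoy PSM such that the expected number
# of decoy protein groups (>= 2 of `per` distinct peptides significant) over
# `n_acc` decoy accessions equals target_fdr * T_hat.
calibrate_decoy_margin <- function(truth, config) {
  per <- config$decoy_psms_per_protein
  n_dec <- round(config$decoy_fraction * config$total_spectra_per_sample)
  n_acc <- 2L * (n_dec %/% per) # decoy accessions are sample-specific
  if (n_acc == 0) {
    return(list(margin = -Inf, p_sig = 0))
  }
  t_hat <- expected_identified_targets(truth, config)
  v <- config$target_protein_fdr * t_hat / n_acc
  v <- min(v, 0.999)
  f <- function(p) pbinom(1, per, p, lower.tail = FALSE) - v
  p_sig <- if (v <= 0) 1e-12 else uniroot(f, c(1e-12, 1 - 1e-12))$root
  list(margin = config$score_sd * qnorm(p_sig), p_sig = p_sig)
}

#' Simulate a peptide-spectrum-match table from a ground truth
#'
#' Draws, for each sample, `total_spectra_per_sample` target spectra by
#' multinomial sampling with probability proportional to baseline abundance
#' (sample A) or abundance times planted fold (sample B). A
#' `leakage_fraction` of each sample's spectra is diverted to contaminant
#' proteins, in proportion to their intracellular abundance. Each spectrum is
#' assigned a peptide drawn uniformly from the protein's inventory, a
#' per-spectrum identity threshold, and a score above the threshold on
#' average by `target_score_margin`.
#'
#' Decoy spectra (extra rows, `decoy_fraction * total_spectra_per_sample` per
#' sample) are grouped into decoy accessions of `decoy_psms_per_protein`
#' distinct peptides each. Their score distribution sits below the threshold
#' distribution by a margin calibrated so the expected protein-level decoy
#' rate among identifications equals `target_protein_fdr`.
#'
#' @param truth A [generate_truth()] result.
#' @param config The same [simulation_config()] that produced `truth`.
#' @return A tibble of PSM records with columns `spectrum_id`, `peptide`,
#'   `protein`, `score`, `identity_threshold`, `is_decoy`, `sample`.
#' @examples
#' cfg <- simulation_config(n_proteins = 50, total_spectra_per_sample = 200, seed = 2)
#' psms <- simulate_psm_table(generate_truth(cfg), cfg)
#' dplyr::count(psms, sample, is_decoy)
#' @export
simulate_psm_table <- function(truth, config) {
  stopifnot(inherits(truth, "speccount_truth"), inherits(config, "speccount_config"))
  if (config$total_spectra_per_sample < 1) {
    abort("`total_spectra_per_sample` must be positive.")
  }
  set.seed(config$seed + 1L)
  depth <- config$total_spectra_per_sample
  decoy_cal <- calibrate_decoy_margin(truth, config)
  out <- vector("list", 2L)

  for (s in 1:2) {
    label <- config$samples[s]
    n_leak <- round(config$leakage_fraction_per_sample[s] * depth)
    w <- sample_weights(truth, s)
    counts <- as.integer(rmultinom(1, depth - n_leak, w))
    if (n_leak > 0 && any(truth$contaminant)) {
      b <- ifelse(truth$contaminant, truth$baseline, 0)
      counts <- counts + as.integer(rmultinom(1, n_leak, b))
    }
    idx <- rep.int(seq_len(nrow(truth)), counts)
    n_t <- length(idx)
    pep_no <- ceiling(runif(n_t) * truth$n_peptides[idx])
    thr <- rnorm(n_t, config$score_location, config$score_spread)
    target <- tibble::tibble(
      spectrum_id = sprintf("S%d_scan%06d", s, seq_len(n_t)),
      peptide = sprintf("%s_PEP%02d", truth$protein[idx], pep_no),
      protein = truth$protein[idx],
      score = thr + rnorm(n_t, config$target_score_margin, config$score_sd),
      identity_threshold = thr,
      is_decoy = FALSE,
      sample = label
    )

    n_dec <- round(config$decoy_fraction * depth)
    if (n_dec > 0) {
      per <- config$decoy_psms_per_protein
      acc_no <- ceiling(seq_len(n_dec) / per)
      within <- (seq_len(n_dec) - 1L) %% per + 1L
      dthr <- rnorm(n_dec, config$score_location, config$score_spread)
      decoy <- tibble::tibble(
        spectrum_id = sprintf("S%d_decoy%06d", s, seq_len(n_dec)),
        peptide = sprintf("DECOY_S%d_%05d_PEP%02d", s, acc_no, within),
        protein = sprintf("DECOY_S%d_%05d", s, acc_no),
        score = dthr + rnorm(n_dec, decoy_cal$margin, config$score_sd),
        identity_threshold = dthr,
        is_decoy = TRUE,
        sample = label
      )
      target <- dplyr::bind_rows(target, decoy)
    }
    out[[s]] <- target
  }
  dplyr::bind_rows(out)
}

#' Annotation sets implied by a simulation truth
#'
#' @param truth A [generate_truth()] result.
#' @return A tibble with columns `category`, `description`, `protein`,
#'   suitable for [enrich_set()] and [write_gmt()].
#' @export
truth_annotations <- function(truth) {
  stopifnot(inherits(truth, "speccount_truth"))
  tibble::tibble(
    category = truth$category,
    description = "simulated annotation",
    protein = truth$protein
  ) |>
    dplyr::arrange(.data$category, .data$protein)
}

#' Simulate a protein-protein interaction network
#'
#' Planted-module graph: module members are densely connected (exactly
#' `ceiling(density * choose(m, 2))` internal edges, sampled without
#' replacement), while the remaining proteome is wired as a sparse random
#' background with the given mean degree (module-background edges allowed).
#'
#' @param truth A [generate_truth()] result.
#' @param module_density Internal edge density of the planted module.
#' @param background_mean_degree Mean degree of the sparse background.
#' @param seed Integer seed (defaults to the truth's configuration seed
#'   offset by 2).
#' @return A tibble edge list with columns `from`, `to` (undirected, no
#'   self-loops, no duplicates).
#' @export
simulate_interactions <- function(truth, module_density = 0.6,
                                  background_mean_degree = 2,
                                  seed = NULL) {
  stopifnot(inherits(truth, "speccount_truth"))
  config <- attr(truth, "config")
  if (is.null(seed)) seed <- config$seed + 2L
  set.seed(seed)
  prots <- truth$protein
  n <- length(prots)
  mod <- truth$protein[truth$module]
  m <- length(mod)

  edges <- list()
  if (m >= 2) {
    pairs <- t(utils::combn(sort(mod), 2))
    n_keep <- ceiling(module_density * nrow(pairs))
    keep <- sample(nrow(pairs), n_keep)
    edges$module <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2])
  }
  n_bg <- round(background_mean_degree * n / 2)
  if (n_bg > 0) {
    a <- sample(prots, 3 * n_bg, replace = TRUE)
    b <- sample(prots, 3 * n_bg, replace = TRUE)
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    ok <- lo != hi & !(lo %in% mod & hi %in% mod)
    bg <- tibble::tibble(from = lo[ok], to = hi[ok]) |> dplyr::distinct()
    edges$background <- head(bg, n_bg)
  }
  dplyr::bind_rows(edges) |> dplyr::distinct()
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits one PSM table per sample, a GMT annotation file, a TSV interaction
#' edge list, and the truth table, all as plain tab-delimited text that
#' round-trips losslessly through the package readers.
#'
#' @param truth A [generate_truth()] result (carries its configuration).
#' @param psms The matching [simulate_psm_table()] output.
#' @param path Directory to write into (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @examples
#' cfg <- simulation_config(n_proteins = 40, total_spectra_per_sample = 150, seed = 3)
#' truth <- generate_truth(cfg)
#' files <- write_fixture_bundle(truth, simulate_psm_table(truth, cfg), tempfile())
#' basename(files)
#' @export
write_fixture_bundle <- function(truth, psms, path) {
  stopifnot(inherits(truth, "speccount_truth"))
  config <- attr(truth, "config")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(sprintf("Cannot create directory '%s'.", path))

  files <- character(0)
  for (label in config$samples) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", label)
    f <- file.path(path, sprintf("psm_%s.tsv", safe))
    write_psm_table(dplyr::filter(psms, .data$sample == label), f)
    files[paste0("psm_", safe)] <- f
  }

  files["gmt"] <- file.path(path, "annotations.gmt")
  write_gmt(truth_annotations(truth), files["gmt"])

  files["edges"] <- file.path(path, "interactions.tsv")
  write_edge_list(simulate_interactions(truth), files["edges"])

  files["truth"] <- file.path(path, "truth.tsv")
  readr::write_tsv(
    dplyr::select(
      tibble::as_tibble(truth),
      "protein", "baseline", "fold", "module", "contaminant"
    ),
    files["truth"]
  )
  invisible(files)
}
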