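with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      parent = e
    )
  })
}

#' Run the full differential secretome pipeline
#'
#' Orchestrates the analysis end to end: score-filters the PSMs, infers
#' protein groups per sample (two-unique-peptide rule) and study-wide
#' (for the target-decoy FDR), quantifies the pair by signed RSc with the
#' five-way partition, runs categorical enrichment of the increased and
#' decreased sets against the detected background, and scores
#' interaction-graph modules for enrichment of the abundant set (unique-to-B
#' plus common proteins at least `fold_cutoff`-fold up in B). Re-running
#' with the same inputs and parameters reproduces identical tables.
#'
#' @param psms PSM table covering both samples (see [read_psm_table()]).
#' @param annotations Optional annotation tibble (`category`, `protein`; see
#'   [read_gmt()]); enables the enrichment stage.
#' @param edges Optional interaction edge list (`from`, `to`); enables the
#'   network stage.
#' @param sample_a,sample_b Labels of the reference (A) and test (B) sample;
#'   default to the first two labels in `psms` in order of appearance.
#' @param min_unique_peptides Protein-inference cut-off, default 2.
#' @param fdr_mode FDR estimator passed to [estimate_fdr()].
#' @param c RSc pseudo-count, default 1.25.
#' @param fold_cutoff Inclusive partition cut-off, default 2.
#' @param high_tier_cutoff Strict high-tier cut-off, default 15.
#' @param alpha Enrichment significance level, default 0.05.
#' @param min_module_size,split_threshold Module-extraction settings (see
#'   [extract_modules()]).
#' @return An object of class `speccount_run`: a list with elements
#'   `groups` (per-sample protein groups), `identification` (FDR summary),
#'   `differential`, `partition`, `enrichment` (named list for the
#'   `increased` and `decreased` sets), `modules`, `params`, and `log`.
#' @examples
#' cfg <- simulation_config(
#'   n_proteins = 120, total_spectra_per_sample = 600,
#'   module_size = 8, seed = 42
#' )
#' truth <- generate_truth(cfg)
#' run <- run_pipeline(
#'   simulate_psm_table(truth, cfg),
#'   annotations = truth_annotations(truth),
#'   edges = simulate_interactions(truth)
#' )
#' glance(run)
#' @export
run_pipeline <- function(psms,
                         annotations = NULL,
                         edges = NULL,
                         sample_a = NULL,
                         sample_b = NULL,
                         min_unique_peptides = 2L,
                         fdr_mode = c("d_over_t", "two_d"),
                         c = 1.25,
                         fold_cutoff = 2,
                         high_tier_cutoff = 15,
                         alpha = 0.05,
                         min_module_size = 3L,
                         split_threshold = 200L) {
  assert_psm_table(psms)
  fdr_mode <- match.arg(fdr_mode)
  labels <- unique(psms$sample)
  sample_a <- sample_a %||% labels[1]
  sample_b <- sample_b %||% labels[2]
  if (is.na(sample_a) || is.na(sample_b) ||
    !all(c(sample_a, sample_b) %in% labels)) {
    abort("`psms` must contain the two requested sample labels.")
  }

  significant <- with_stage("identification", filter_significant_psms(psms))
  groups <- with_stage("identification", list(
    A = infer_proteins(
      dplyr::filter(significant, .data$sample == sample_a),
      min_unique_peptides
    ),
    B = infer_proteins(
      dplyr::filter(significant, .data$sample == sample_b),
      min_unique_peptides
    )
  ))
  identification <- with_stage(
    "identification",
    estimate_fdr(
      infer_proteins(significant, min_unique_peptides),
      mode = fdr_mode
    )
  )

  differential <- with_stage(
    "quantitation",
    quantify_pair(groups$A, groups$B,
      c = c, fold_cutoff = fold_cutoff,
      high_tier_cutoff = high_tier_cutoff
    )
  )
  partition <- with_stage("quantitation", summarize_partition(differential))

  background <- differential$protein
  increased <- differential$protein[
    differential$partition %in% c("unique_B", "common_higher_B")
  ]
  decreased <- differential$protein[
    differential$partition %in% c("unique_A", "common_lower_B")
  ]

  enrichment <- NULL
  if (!is.null(annotations)) {
    enrichment <- with_stage("enrichment", {
      run_one <- function(query) {
        if (length(query) == 0) {
          return(NULL)
        }
        enrich_set(query, background, annotations, alpha = alpha)
      }
      list(increased = run_one(increased), decreased = run_one(decreased))
    })
  }

  modules <- NULL
  if (!is.null(edges)) {
    modules <- with_stage("network", {
      graph <- build_graph(edges, restrict_to = background)
      found <- extract_modules(graph,
        min_size = min_module_size,
        split_threshold = split_threshold
      )
      score_modules(found, intersect(increased, background), background)
    })
  }

  params <- list(
    sample_a = sample_a, sample_b = sample_b,
    min_unique_peptides = as.integer(min_unique_peptides),
    fdr_mode = fdr_mode, c = c,
    fold_cutoff = fold_cutoff, high_tier_cutoff = high_tier_cutoff,
    alpha = alpha, min_module_size = as.integer(min_module_size),
    split_threshold = as.integer(split_threshold)
  )
  log <- c(
    sprintf("speccount %s", as.character(utils::packageVersion("speccount"))),
    sprintf("samples: A='%s' (reference), B='%s' (test)", sample_a, sample_b),
    sprintf("psms: %d total, %d significant (score > identity threshold)",
      nrow(psms), nrow(significant)
    ),
    sprintf("min_unique_peptides=%d, fdr_mode=%s", params$min_unique_peptides,
      fdr_mode
    ),
    sprintf("c=%g, fold_cutoff=%g, high_tier_cutoff=%g", c, fold_cutoff,
      high_tier_cutoff
    ),
    sprintf("alpha=%g, min_module_size=%d, split_threshold=%d", alpha,
      params$min_module_size, params$split_threshold
    ),
    sprintf("identified: %d target proteins, %d decoy, fdr=%.5f",
      identification$n_target_proteins, identification$n_decoy_proteins,
      identification$fdr
    )
  )

  structure(
    list(
      groups = groups,
      identification = identification,
      differential = differential,
      partition = partition,
      enrichment = enrichment,
      modules = modules,
      params = params,
      log = log
    ),
    class = "speccount_run"
  )
}

#' Write every table of a pipeline run to a directory
#'
#' Emits the per-sample protein-group TSVs, the differential TSV, the JSON
#' partition and identification summaries, the enrichment TSVs, the module
#' TSVs, and a plain-text run log recording every threshold applied.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "speccount_run"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(sprintf("Cannot create directory '%s'.", dir))
  paths <- character(0)

  paths["groups_a"] <- file.path(dir, "protein_groups_A.tsv")
  write_protein_groups(run$groups$A, paths["groups_a"])
  paths["groups_b"] <- file.path(dir, "protein_groups_B.tsv")
  write_protein_groups(run$groups$B, paths["groups_b"])

  paths["differential"] <- file.path(dir, "differential.tsv")
  write_differential(run$differential, paths["differential"])

  paths["summary"] <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(
      identification = as.list(run$identification),
      partition = as.list(run$partition),
      params = run$params
    ),
    paths["summary"],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  for (set in names(run$enrichment %||% list())) {
    if (is.null(run$enrichment[[set]])) next
    key <- paste0("enrichment_", set)
    paths[key] <- file.path(dir, paste0(key, ".tsv"))
    write_enrichment(run$enrichment[[set]], paths[key])
  }

  if (!is.null(run$modules)) {
    paths["modules"] <- file.path(dir, "module_members.tsv")
    run$modules |>
      dplyr::select("module", "members") |>
      tidyr::unnest(cols = "members") |>
      dplyr::rename(protein = "members") |>
      readr::write_tsv(paths["modules"], progress = FALSE)
    paths["module_scores"] <- file.path(dir, "module_scores.tsv")
    run$modules |>
      dplyr::select(-"members") |>
      dplyr::mutate(
        density = sprintf("%.4f", .data$density),
        fold = sprintf("%.4f", .data$fold),
        p_value = sprintf("%.6e", .data$p_value),
        q_value = sprintf("%.6e", .data$q_value)
      ) |>
      readr::write_tsv(paths["module_scores"], progress = FALSE)
  }

  paths["log"] <- file.path(dir, "run_log.txt")
  writeLines(run$log, paths["log"])
  invisible(paths)
}

#' @export
print.speccount_run <- function(x, ...) {
  cat("<speccount_run>\n")
  cat(paste0("  ", x$log), sep = "\n")
  p <- x$partition
  cat(sprintf(
    "  partition: %d unique A | %d common (%d higher B, %d lower B) | %d unique B; total %d\n",
    p$n_unique_a, p$n_common, p$n_common_higher_b, p$n_common_lower_b,
    p$n_unique_b, p$n_total
  ))
  cat(sprintf(
    "  increased in B (unique B + >=%g-fold common): %d proteins\n",
    x$params$fold_cutoff, p$n_increased_b
  ))
  if (!is.null(x$modules) && nrow(x$modules) > 0) {
    top <- x$modules[1, ]
    cat(sprintf(
      "  top module: %s (%d members, density %.2f, p=%.3g)\n",
      top$module, top$n_members, top$density, top$p_value
    ))
  }
  invisible(x)
}

#' Tidy the differential table of a pipeline run
#'
#' @param x A `speccount_run`.
#' @param ... Unused.
#' @return The per-protein differential tibble.
#' @method tidy speccount_run
#' @export
tidy.speccount_run <- function(x, ...) {
  x$differential
}

#' One-row summary of a pipeline run
#'
#' @param x A `speccount_run`.
#' @param ... Unused.
#' @return A one-row tibble combining the identification and partition
#'   summaries.
#' @method glance speccount_run
#' @export
glance.speccount_run <- function(x, ...) {
  dplyr::bind_cols(x$identification, x$partition)
}
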