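#' Fold enrichment of a category in a query set
#'
#' The ratio of the category's frequency in the query to its frequency in the
#' background: `(k/n) / (K/N)`. Returns 0 when the overlap `k` is 0.
#'
#' @param k Overlap count (query members in the category).
#' @param n Query size.
#' @param K Category size within the background.
#' @param N Background size.
#' @return Numeric vector of fold enrichments.
#' @examples
#' fold_enrichment(10, 20, 10, 200) # 10-fold
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_hyper_args(k, n, K, N)
  (k / n) / (K / N)
}

check_hyper_args <- function(k, n, K, N) {
  if (any(n == 0) || any(K == 0) || any(N == 0)) {
    abort("`n`, `K` and `N` must be positive.")
  }
  if (any(k < 0) || any(n > N) || any(K > N)) {
    abort("Need 0 <= k, n <= N and K <= N.")
  }
  if (any(k > pmin(n, K))) {
    abort("Infeasible overlap: `k` exceeds min(n, K).")
  }
  invisible(TRUE)
}

#' Hypergeometric tail test for set enrichment or depletion
#'
#' For `X ~ Hypergeometric(N, K, n)` (drawing `n` from a background of `N`
#' containing `K` category members), the enriched direction returns
#' `P[X >= k]` and the depleted direction `P[X <= k]`.
#'
#' @inheritParams fold_enrichment
#' @param direction `"enriched"` or `"depleted"`.
#' @return Numeric vector of tail probabilities.
#' @examples
#' hypergeom_test(3, 3, 4, 10, "enriched") # 4/120
#' hypergeom_test(0, 3, 3, 6, "depleted") # 1/20
#' @export
hypergeom_test <- function(k, n, K, N, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  check_hyper_args(k, n, K, N)
  if (direction == "enriched") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n)
  }
}

#' Test annotation categories for enrichment or depletion in a query set
#'
#' For every category with at least one member in the background, computes
#' the overlap with the query, the fold enrichment, a one-sided
#' hypergeometric p-value in the direction suggested by the fold (enriched
#' when fold >= 1, depleted otherwise), and Benjamini-Hochberg q-values
#' across all tested categories within each vocabulary. Annotations are
#' restricted to the background before testing; unannotated background
#' proteins still count toward `N`.
#'
#' @param query Character vector of protein accessions; must be a subset of
#'   `background`.
#' @param background Character vector of accessions defining the tested
#'   universe (typically every protein detected in either sample).
#' @param annotations Data frame with columns `category` and `protein`
#'   (optional `vocabulary` column; q-values are adjusted per vocabulary).
#' @param alpha Significance level used to flag `significant = q_value < alpha`.
#' @return A tibble sorted by `p_value` (ties: descending `fold`, then
#'   category name) with columns `category`, `k`, `n`, `K`, `N`, `fold`,
#'   `p_value`, `q_value`, `direction`, `significant` (and `vocabulary` if
#'   supplied).
#' @examples
#' ann <- tibble::tibble(
#'   category = rep(c("protease", "adhesion"), c(3, 3)),
#'   protein = c("P1", "P2", "P3", "P4", "P5", "P6")
#' )
#' enrich_set(c("P1", "P2", "P3"), paste0("P", 1:10), ann)
#' @export
enrich_set <- function(query, background, annotations, alpha = 0.05) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(query) == 0) abort("`query` must contain at least one accession.")
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    abort(sprintf(
      "`query` is not a subset of `background`; offending accession(s): %s%s.",
      paste(head(stray, 5), collapse = ", "),
      if (length(stray) > 5) sprintf(" (+%d more)", length(stray) - 5) else ""
    ))
  }
  stopifnot(is.data.frame(annotations))
  if (!all(c("category", "protein") %in% names(annotations))) {
    abort("`annotations` needs columns `category` and `protein`.")
  }
  has_vocab <- "vocabulary" %in% names(annotations)
  ann <- annotations |>
    dplyr::filter(.data$protein %in% background) |>
    dplyr::distinct(
      dplyr::across(dplyr::any_of(c("vocabulary", "category", "protein")))
    )
  if (!has_vocab) ann$vocabulary <- "default"

  res <- ann |>
    dplyr::group_by(.data$vocabulary, .data$category) |>
    dplyr::summarise(
      k = sum(.data$protein %in% query),
      K = dplyr::n(),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(
      n = length(query),
      N = length(background),
      fold = fold_enrichment(.data$k, .data$n, .data$K, .data$N),
      direction = ifelse(.data$fold >= 1, "enriched", "depleted"),
      p_value = ifelse(
        .data$direction == "enriched",
        hypergeom_test(.data$k, .data$n, .data$K, .data$N, "enriched"),
        hypergeom_test(.data$k, .data$n, .data$K, .data$N, "depleted")
      ),
      q_value = p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q_value < alpha) |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$fold), .data$category) |>
    dplyr::select(
      dplyr::any_of("vocabulary"), "category", "k", "n", "K", "N",
      "fold", "p_value", "q_value", "direction", "significant"
    )
  if (!has_vocab) res$vocabulary <- NULL
  class(res) <- c("speccount_enrichment", class(res))
  res
}
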