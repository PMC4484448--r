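#' Build an undirected protein-interaction graph from an edge list
#'
#' Drops self-loops, collapses duplicate edges regardless of orientation,
#' optionally restricts to an induced subgraph, and drops isolated nodes.
#' Vertices are ordered lexicographically so downstream clustering is
#' reproducible for any input row order.
#'
#' @param edges Data frame whose first two columns (or columns `from`/`to`)
#'   are protein accessions.
#' @param restrict_to Optional character vector; keep only edges with both
#'   endpoints in this set.
#' @return An [igraph::igraph] object.
#' @examples
#' g <- build_graph(tibble::tibble(
#'   from = c("A", "B", "A", "A"),
#'   to = c("B", "A", "A", "C")
#' ))
#' igraph::gsize(g) # 2: A-B deduplicated, A-A dropped
#' @export
build_graph <- function(edges, restrict_to = NULL) {
  stopifnot(is.data.frame(edges))
  if (all(c("from", "to") %in% names(edges))) {
    e <- edges[c("from", "to")]
  } else if (ncol(edges) >= 2) {
    e <- stats::setNames(edges[1:2], c("from", "to"))
  } else {
    abort("`edges` must have at least two columns (from, to).")
  }
  e$from <- as.character(e$from)
  e$to <- as.character(e$to)
  bad <- which(is.na(e$from) | is.na(e$to) | !nzchar(e$from) | !nzchar(e$to))
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed edge row(s): %s.",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  e <- tibble::tibble(from = pmin(e$from, e$to), to = pmax(e$from, e$to)) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::distinct()
  if (!is.null(restrict_to)) {
    e <- dplyr::filter(e, .data$from %in% restrict_to & .data$to %in% restrict_to)
  }
  verts <- sort(unique(c(e$from, e$to)))
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = verts)
}

#' Extract dense modules from an interaction graph
#'
#' Connected components are computed first; components larger than
#' `split_threshold` are partitioned further by greedy modularity
#' maximization, and each resulting community is trimmed to its `core`-core
#' (members with at least `core` connections inside the community). The trim
#' matters because modularity clustering absorbs sparsely attached
#' neighbours of a dense cluster; requiring a minimum internal degree strips
#' those pendants and leaves the dense core the stage is after. Small whole
#' components are kept as-is. Modules smaller than `min_size` are discarded.
#' The result is deterministic for a given graph (vertices are ordered
#' lexicographically by [build_graph()]); modules are numbered by decreasing
#' size, ties broken by the lexicographically smallest member.
#'
#' @param graph An [igraph::igraph], e.g. from [build_graph()].
#' @param min_size Smallest module to keep (>= 2); default 3.
#' @param split_threshold Components above this size are split by greedy
#'   modularity; default 200.
#' @param core Minimum within-community degree kept after splitting a large
#'   component; default 3.
#' @return A tibble with one row per module: `module`, `n_members`,
#'   `n_edges`, `density` (`2E / (m (m - 1))`), and a `members` list-column.
#' @examples
#' tri2 <- tibble::tibble(
#'   from = c("A", "B", "C", "X", "Y", "Z"),
#'   to = c("B", "C", "A", "Y", "Z", "X")
#' )
#' extract_modules(build_graph(tri2))
#' @export
extract_modules <- function(graph, min_size = 3L, split_threshold = 200L,
                            core = 3L) {
  stopifnot(inherits(graph, "igraph"))
  if (min_size < 2) abort("`min_size` must be >= 2.")
  if (igraph::vcount(graph) == 0) {
    return(empty_modules())
  }
  comps <- igraph::components(graph)
  member_sets <- list()
  for (ci in seq_len(comps$no)) {
    nodes <- names(which(comps$membership == ci))
    if (length(nodes) > split_threshold) {
      sub <- igraph::induced_subgraph(graph, nodes)
      cl <- igraph::cluster_fast_greedy(sub)
      ms <- split(igraph::V(sub)$name, igraph::membership(cl))
      ms <- lapply(ms, function(members) {
        community <- igraph::induced_subgraph(graph, members)
        deg <- igraph::coreness(community)
        names(deg)[deg >= core]
      })
      member_sets <- c(member_sets, unname(ms))
    } else {
      member_sets <- c(member_sets, list(nodes))
    }
  }
  member_sets <- lapply(member_sets, sort)
  member_sets <- member_sets[lengths(member_sets) >= min_size]
  if (length(member_sets) == 0) {
    return(empty_modules())
  }
  ord <- order(-lengths(member_sets), vapply(member_sets, `[`, "", 1))
  member_sets <- member_sets[ord]
  purrr::imap_dfr(member_sets, function(members, i) {
    m <- length(members)
    e <- igraph::gsize(igraph::induced_subgraph(graph, members))
    tibble::tibble(
      module = sprintf("M%03d", i),
      n_members = m,
      n_edges = e,
      density = 2 * e / (m * (m - 1)),
      members = list(members)
    )
  })
}

empty_modules <- function() {
  tibble::tibble(
    module = character(), n_members = integer(), n_edges = integer(),
    density = numeric(), members = list()
  )
}

#' Score modules for enrichment of an abundant protein set
#'
#' For each module, tests whether its members overlap the designated
#' "abundant" set more than expected under hypergeometric sampling from the
#' background: `k` abundant members out of `n` module members in the
#' background, against `K = |abundant|`, `N = |background|`. q-values are
#' Benjamini-Hochberg across modules; results are sorted by p-value.
#'
#' @param modules Output of [extract_modules()].
#' @param abundant_set Accessions of the high-abundance proteins (e.g.
#'   unique-to-B plus common proteins at least 2-fold up in B).
#' @param background Accessions of the tested universe; `abundant_set` must
#'   be a subset.
#' @return `modules` with added columns `k`, `fold`, `p_value`, `q_value`,
#'   sorted by `p_value`.
#' @export
score_modules <- function(modules, abundant_set, background) {
  stopifnot(is.data.frame(modules), "members" %in% names(modules))
  background <- unique(as.character(background))
  abundant_set <- unique(as.character(abundant_set))
  if (length(background) == 0) abort("`background` must be non-empty.")
  stray <- setdiff(abundant_set, background)
  if (length(stray) > 0) {
    abort(sprintf(
      "`abundant_set` is not a subset of `background` (e.g. %s).",
      paste(head(stray, 3), collapse = ", ")
    ))
  }
  if (nrow(modules) == 0) {
    return(dplyr::mutate(modules,
      k = integer(), fold = numeric(),
      p_value = numeric(), q_value = numeric()
    ))
  }
  K <- length(abundant_set)
  N <- length(background)
  modules |>
    dplyr::mutate(
      n_in_background = purrr::map_int(
        .data$members, ~ length(intersect(.x, background))
      ),
      k = purrr::map_int(
        .data$members, ~ length(intersect(.x, abundant_set))
      ),
      fold = fold_enrichment(.data$k, .data$n_in_background, K, N),
      p_value = hypergeom_test(.data$k, .data$n_in_background, K, N, "enriched"),
      q_value = p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::select(-"n_in_background") |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$fold), .data$module)
}
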