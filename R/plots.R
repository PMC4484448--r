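#' Bar chart of the five-way differential partition
#'
#' @param records A differential tibble from [quantify_pair()], or a
#'   `speccount_run`.
#' @return A ggplot.
#' @export
plot_partition <- function(records) {
  if (inherits(records, "speccount_run")) records <- records$differential
  stopifnot(is.data.frame(records), "partition" %in% names(records))
  counts <- records |>
    dplyr::count(partition = factor(.data$partition, levels = partition_levels),
      .drop = FALSE
    )
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$partition, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = NULL, y = "proteins",
      title = "Differential partition of the detected secretome"
    ) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of signed RSc values
#'
#' Proteins ranked by signed RSc, coloured by partition; horizontal guides
#' mark +/- the 2-fold cut-off.
#'
#' @param records A differential tibble from [quantify_pair()].
#' @param fold_cutoff Cut-off drawn as guide lines, default 2.
#' @return A ggplot.
#' @export
plot_differential <- function(records, fold_cutoff = 2) {
  stopifnot(is.data.frame(records), "rsc_signed" %in% names(records))
  df <- records |>
    dplyr::arrange(.data$rsc_signed) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data$rsc_signed,
    colour = .data$partition
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(
      yintercept = c(-fold_cutoff, fold_cutoff),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "protein rank", y = "signed RSc",
      title = "Signed RSc across the detected secretome"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of category fold enrichment
#'
#' Top categories by p-value; depleted categories are drawn with negative
#' fold so enrichment and depletion read in opposite directions.
#'
#' @param records An enrichment tibble from [enrich_set()].
#' @param top_n Number of categories to show, default 10.
#' @return A ggplot.
#' @export
plot_enrichment <- function(records, top_n = 10) {
  stopifnot(is.data.frame(records), all(c("category", "fold") %in% names(records)))
  df <- records |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(
      signed_fold = ifelse(.data$direction == "depleted", -.data$fold, .data$fold),
      category = factor(.data$category, levels = rev(.data$category))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$signed_fold, y = .data$category,
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "fold enrichment (depletion negative)", y = NULL,
      title = "Category enrichment"
    ) +
    ggplot2::theme_minimal()
}

#' Module enrichment overview
#'
#' Each module as a point: internal edge density against the evidence that
#' its members are over-represented among the abundant proteins.
#'
#' @param modules A scored module tibble from [score_modules()].
#' @return A ggplot.
#' @export
plot_modules <- function(modules) {
  stopifnot(is.data.frame(modules), all(c("density", "p_value") %in% names(modules)))
  ggplot2::ggplot(modules, ggplot2::aes(
    x = .data$density, y = -log10(.data$p_value),
    size = .data$n_members
  )) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::labs(
      x = "module edge density", y = "-log10 p (abundant-set enrichment)",
      title = "Interaction modules"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot speccount_run
#' @export
autoplot.speccount_run <- function(object, ...) {
  plot_partition(object)
}

#' @method autoplot speccount_enrichment
#' @export
autoplot.speccount_enrichment <- function(object, ...) {
  plot_enrichment(object, ...)
}
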