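#' Plot pathway-analysis results
#'
#' Dot plot of pathways against -log10 adjusted p, colored by direction and
#' shaped by the optimized flag — the conventional overview of a two-group
#' pathway screen.
#'
#' @param object A `pathway_results` tibble from [analyze_pathways()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_results <- function(object, ...) {
  df <- tibble::as_tibble(object)
  alpha <- attr(object, "alpha") %||% 0.01
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_adj),
    y = stats::reorder(.data$pathway, -.data$p_adj),
    color = .data$direction, shape = .data$optimized
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  color = "direction", shape = "optimized") +
    ggplot2::theme_minimal()
}

#' Plot per-gene importance scores for one pathway
#'
#' @param importance Tibble from [importance_scores()].
#' @param top_n Show the top genes by scaled importance (default all).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = Inf) {
  df <- importance |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$gene, .data$importance)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "scaled importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of gene activity across attractors
#'
#' Mean per-gene activity (0-1, cycle average) for each attractor — the
#' ON/OFF table used to characterize signaling states.
#'
#' @param attractors Tibble from [harvest_attractors()] (or list of
#'   `attractor`s).
#' @param genes Optional subset of genes to show.
#' @return A ggplot object.
#' @export
plot_attractor_profiles <- function(attractors, genes = NULL) {
  if (is.data.frame(attractors)) attractors <- attractors$attractor
  df <- purrr::imap_dfr(attractors, function(a, i) {
    tibble::tibble(attractor = paste0("A", i), gene = names(a$mean_state),
                   activity = unname(a$mean_state))
  })
  if (!is.null(genes)) df <- dplyr::filter(df, .data$gene %in% toupper(genes))
  ggplot2::ggplot(df, ggplot2::aes(.data$attractor, .data$gene,
                                   fill = .data$activity)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "#9ecae1", high = "#de2d26",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "activity") +
    ggplot2::theme_minimal()
}

#' Plot attractor occupancy by subject or group
#'
#' @param assignment An `attractor_assignment`.
#' @param by `"subject"` or `"group"`.
#' @param min_count Attractors with fewer cells are pooled into "other".
#' @return A ggplot object.
#' @export
plot_assignment <- function(assignment, by = c("subject", "group"),
                            min_count = 5) {
  by <- match.arg(by)
  stopifnot(by %in% names(assignment))
  counts <- table(assignment$attractor)
  df <- assignment |>
    dplyr::mutate(attractor = ifelse(counts[.data$attractor] >= min_count,
                                     .data$attractor, "other"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[by]], fill = .data$attractor)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(y = "fraction of cells", x = NULL, fill = "attractor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot mean ERS size against training-set size
#'
#' @param ers Tibble from [ers_vs_cells()].
#' @return A ggplot object.
#' @export
plot_ers_vs_cells <- function(ers) {
  df <- ers |>
    dplyr::group_by(.data$fraction, .data$indegree) |>
    dplyr::summarise(mean_ers = mean(.data$mean_ers), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fraction), .data$mean_ers,
                                   group = factor(.data$indegree),
                                   color = factor(.data$indegree))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of training cells", y = "mean ERS size",
                  color = "in-degree") +
    ggplot2::theme_minimal()
}
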