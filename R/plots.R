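#' Plot network metric medians against the link threshold
#'
#' Reproduces the threshold-sensitivity view of the analysis: per diversity
#' level, the median of each metric across subsampling combinations as a
#' function of the link threshold.
#'
#' @param metrics Long metrics tibble (columns `combination_id`, `level`,
#'   `threshold`, `metric`, `value`), as written by [run_full_analysis()].
#' @param which_metrics Metrics to show (default: OTU number, connectance,
#'   generality, C score).
#' @return A ggplot object.
#' @export
plot_threshold_trends <- function(metrics,
                                  which_metrics = c("n_otus", "connectance",
                                                    "generality", "c_score")) {
  df <- metrics |>
    dplyr::filter(.data$metric %in% which_metrics, !is.na(.data$value)) |>
    dplyr::group_by(.data$level, .data$threshold, .data$metric) |>
    dplyr::summarise(median = median(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$median,
                                   colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "co-occurrence link threshold (of 5 samples)",
                  y = "median across combinations", colour = "tree diversity")
}

#' Boxplots of per-combination median phi by tree diversity level
#'
#' @param phi_medians Tibble with columns `level` and `median_positive_phi`
#'   (one row per combination and level), as written by
#'   [run_full_analysis()].
#' @return A ggplot object.
#' @export
plot_phi_levels <- function(phi_medians) {
  df <- dplyr::filter(phi_medians, !is.na(.data$median_positive_phi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level,
                                   y = .data$median_positive_phi)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "tree diversity level",
                  y = "median positive phi per combination")
}

#' Boxplots of positive phi by fungal functional guild
#'
#' @param phi_records Tibble with columns `otu_id` and `phi`.
#' @param guilds Guild tibble (see [read_guild_map()]).
#' @return A ggplot object.
#' @export
plot_guild_phi <- function(phi_records, guilds) {
  df <- phi_records |>
    dplyr::filter(!is.na(.data$phi), .data$phi > 0) |>
    dplyr::mutate(guild = guild_of(guilds, .data$otu_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$guild, y = .data$phi)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "fungal functional group", y = "positive phi") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heatmap of the top specialist OTUs
#'
#' Tile map of the per-species maximum phi of the top-ranked specialists,
#' rows in hierarchical-clustering order (see [rank_specialists()]).
#'
#' @param specialists Result of [rank_specialists()].
#' @return A ggplot object.
#' @export
plot_specialist_heatmap <- function(specialists) {
  m <- specialists$matrix
  df <- tibble::as_tibble(m, rownames = "otu_id") |>
    tidyr::pivot_longer(cols = !"otu_id", names_to = "tree_species",
                        values_to = "phi") |>
    dplyr::mutate(otu_id = factor(.data$otu_id, levels = rev(rownames(m))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tree_species, y = .data$otu_id,
                                   fill = .data$phi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "tree species", y = "fungal OTU", fill = "max phi") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a bipartite web as an incidence grid
#'
#' @param x A `tw_web` from [build_web()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tw_web <- function(x, ...) {
  m <- unclass(x)
  attr(m, "threshold") <- NULL
  df <- tibble::as_tibble(m, rownames = "tree_species") |>
    tidyr::pivot_longer(cols = !"tree_species", names_to = "otu_id",
                        values_to = "link")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$otu_id, y = .data$tree_species,
                                   fill = factor(.data$link))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey20")) +
    ggplot2::labs(x = "fungal OTU", y = "tree species", fill = "link") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
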