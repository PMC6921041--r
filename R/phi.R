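#' Phi specialization coefficient of a 2x2 contingency table
#'
#' phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)), equivalently
#' sign(ad - bc) * sqrt(X^2 / N) with X^2 the chi-square statistic of the
#' table. In pipeline use, a counts occurrences of a fungal OTU in the plot
#' containing a given tree species, b occurrences in the other plots, c and
#' d the corresponding absences. Ranges from -1 (complete avoidance) to 1
#' (complete association); undefined (NA) when any margin is zero.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The phi coefficient, or `NA` when a margin is zero.
#' @export
phi_coefficient <- function(a, b, c, d) {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  denom2 <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- ifelse(denom2 > 0, (a * d - b * c) / sqrt(denom2), NA_real_)
  out
}

# Plot-level presence of every OTU across the cells of one combination
# level: a matrix OTU x plot with entry 1 when the OTU occurs in at least
# `presence_min` of the cell's five samples.
plot_presence <- function(incidence, cells, metadata, presence_min = 1L) {
  pres <- matrix(0L, nrow = nrow(incidence), ncol = nrow(cells),
                 dimnames = list(rownames(incidence), cells$species))
  for (i in seq_len(nrow(cells))) {
    ids <- cell_sample_ids(metadata, cells$plot_id[i], cells$species[i],
                           colnames(incidence))
    pres[, i] <- as.integer(rowSums(incidence[, ids, drop = FALSE]) >= presence_min)
  }
  pres
}

#' Phi coefficients of all OTUs for all tree species of a combination level
#'
#' For one combination at one diversity level (k plots, one tree species
#' each; k = 7 in the full design), an OTU's presence per plot is scored
#' (present in at least `presence_min` of the plot's five samples), and for
#' every (OTU present in >= 1 plot) x (tree species) pair the 2x2 table is
#' formed: a = presence in the species' plot, b = presences among the other
#' plots, c = 1 - a, d = (k - 1) - b. Phi is NA when a margin is zero (e.g.
#' an OTU present in every plot).
#'
#' @param incidence Binary incidence matrix (OTUs x samples).
#' @param cells Tibble of (plot_id, species) cells for one combination level.
#' @param metadata Sample metadata tibble.
#' @param presence_min Samples (of 5) required for plot-level presence
#'   (default 1).
#' @return A tibble: `otu_id`, `tree_species`, `phi`.
#' @export
phi_table <- function(incidence, cells, metadata, presence_min = 1L) {
  pres <- plot_presence(incidence, cells, metadata, presence_min)
  occ <- rowSums(pres)
  pres <- pres[occ > 0, , drop = FALSE]
  occ <- occ[occ > 0]
  k <- nrow(cells)
  if (nrow(pres) == 0) {
    return(tibble::tibble(otu_id = character(0), tree_species = character(0),
                          phi = numeric(0)))
  }
  # vectorized over the OTU x species grid
  a <- as.vector(pres)                         # OTU-major, species blocks
  b <- rep(unname(occ), times = k) - a
  phi <- phi_coefficient(a, b, 1 - a, (k - 1) - b)
  tibble::tibble(
    otu_id = rep(rownames(pres), times = k),
    tree_species = rep(cells$species, each = nrow(pres)),
    phi = phi
  )
}

#' Median of the positive phi coefficients
#'
#' The per-combination specialization summary: the median of all defined,
#' strictly positive phi values of one (combination, level).
#'
#' @param phi Numeric vector of phi values (NA = undefined allowed).
#' @return The median, or `NA` if there is no positive defined value.
#' @export
median_positive_phi <- function(phi) {
  pos <- phi[!is.na(phi) & phi > 0]
  if (length(pos) == 0) return(NA_real_)
  median(pos)
}

#' Compare specialization between fungal functional groups
#'
#' Kruskal-Wallis test over the positive phi values grouped by guild, with
#' Siegel-Castellan pairwise post hoc comparisons (Bonferroni by default,
#' matching the specialization analysis; Holm available).
#'
#' @param phi_records Tibble with columns `otu_id` and `phi`.
#' @param guilds Guild tibble (see [read_guild_map()]).
#' @param min_group_n Guilds with fewer positive phi values are dropped.
#' @param alpha Significance level for the post hoc comparisons.
#' @param correction Passed to [kruskal_posthoc()].
#' @return A list: `kruskal` (`tw_kruskal`), `posthoc` (pairwise tibble),
#'   `group_medians` (tibble guild/n/median_phi).
#' @export
group_phi_comparison <- function(phi_records, guilds, min_group_n = 1L,
                                 alpha = 0.05,
                                 correction = c("bonferroni", "holm")) {
  correction <- match.arg(correction)
  tb <- phi_records |>
    dplyr::filter(!is.na(.data$phi), .data$phi > 0) |>
    dplyr::mutate(guild = guild_of(guilds, .data$otu_id))
  groups <- split(tb$phi, tb$guild)
  groups <- groups[lengths(groups) >= min_group_n]
  if (length(groups) < 2) stop("need >= 2 guilds with positive phi values",
                               call. = FALSE)
  medians <- tibble::tibble(
    guild = names(groups),
    n = lengths(groups),
    median_phi = unname(vapply(groups, median, numeric(1)))
  )
  list(kruskal = kruskal_wallis(groups),
       posthoc = kruskal_posthoc(groups, alpha = alpha, correction = correction),
       group_medians = medians)
}

#' Rank and cluster the most specialized OTUs
#'
#' For every OTU the maximum phi across species and combinations is taken;
#' the `top_n` OTUs by maximum phi (ties broken by OTU id) are arranged in
#' an OTU x tree-species matrix of per-species maximum phi, with rows
#' ordered by average-linkage hierarchical clustering on Euclidean
#' distances.
#'
#' @param phi_records Tibble with columns `otu_id`, `tree_species`, `phi`.
#' @param top_n Number of top specialists to keep (default 200).
#' @return A list: `matrix` (phi matrix, clustering row order), `ranking`
#'   (tibble otu_id/max_phi, selection order), `hclust` (the clustering).
#' @export
rank_specialists <- function(phi_records, top_n = 200L) {
  if (nrow(phi_records) == 0) stop("no phi records", call. = FALSE)
  ranking <- phi_records |>
    dplyr::filter(!is.na(.data$phi)) |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(max_phi = max(.data$phi), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$max_phi), .data$otu_id) |>
    dplyr::slice_head(n = top_n)
  wide <- phi_records |>
    dplyr::filter(.data$otu_id %in% ranking$otu_id, !is.na(.data$phi)) |>
    dplyr::group_by(.data$otu_id, .data$tree_species) |>
    dplyr::summarise(phi = max(.data$phi), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "tree_species", values_from = "phi",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$otu_id
  m <- m[ranking$otu_id, , drop = FALSE]
  if (nrow(m) > 2) {
    hc <- hclust(dist(m, method = "euclidean"), method = "average")
    m <- m[hc$order, , drop = FALSE]
  } else {
    hc <- NULL
  }
  list(matrix = m, ranking = ranking, hclust = hc)
}

#' Classify frequent OTUs
#'
#' An OTU is frequent at a diversity level if in at least one subsampling
#' combination it occurs in all k plots of that level. Returns the per
#' (OTU, level) flag together with the maximum plot-occupancy observed, so
#' occupancy histograms for "unique frequent" OTUs (frequent at exactly one
#' level) can be drawn.
#'
#' @param incidence Binary incidence matrix (OTUs x samples).
#' @param combos Long combination tibble from [enumerate_combinations()].
#' @param metadata Sample metadata tibble.
#' @param presence_min Plot-level presence rule, as in [phi_table()].
#' @return A list: `flags` (tibble otu_id/level/max_occupancy/frequent),
#'   `frequent_all_levels` (character vector of OTUs frequent at every
#'   level), `unique_frequent` (tibble of OTUs frequent at exactly one
#'   level, with that level).
#' @export
frequent_otus <- function(incidence, combos, metadata, presence_min = 1L) {
  if (nrow(combos) == 0) stop("no combinations", call. = FALSE)
  levels_present <- unique(combos$level)
  ids <- unique(combos$combination_id)
  res <- list()
  for (lv in levels_present) {
    max_occ <- rep(0L, nrow(incidence))
    k <- NULL
    for (id in ids) {
      cells <- combination_cells(combos, id, lv)
      k <- nrow(cells)
      occ <- rowSums(plot_presence(incidence, cells, metadata, presence_min))
      max_occ <- pmax(max_occ, occ)
    }
    res[[lv]] <- tibble::tibble(otu_id = rownames(incidence), level = lv,
                                max_occupancy = as.integer(max_occ),
                                frequent = max_occ == k)
  }
  flags <- dplyr::bind_rows(res)
  per_otu <- flags |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(n_frequent = sum(.data$frequent), .groups = "drop")
  frequent_all <- per_otu$otu_id[per_otu$n_frequent == length(levels_present)]
  unique_frequent <- flags |>
    dplyr::filter(.data$frequent,
                  .data$otu_id %in% per_otu$otu_id[per_otu$n_frequent == 1]) |>
    dplyr::select("otu_id", "level")
  list(flags = flags, frequent_all_levels = sort(frequent_all),
       unique_frequent = unique_frequent)
}
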