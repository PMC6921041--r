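#' Build the plot design from sample metadata
#'
#' Collapses sample records to one row per plot, recording the species
#' planted (= observed in the metadata) and the plot richness. A plot whose
#' observed species count disagrees with its declared `plot_richness` is an
#' error.
#'
#' @param metadata Sample metadata tibble (see [read_sample_metadata()]).
#' @return A tibble with columns `plot_id`, `richness`, and a list-column
#'   `species`, sorted by (richness, plot_id).
#' @export
build_design <- function(metadata) {
  metadata <- validate_sample_metadata(metadata)
  design <- metadata |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      richness = unique(.data$plot_richness)[1],
      n_declared = dplyr::n_distinct(.data$plot_richness),
      species = list(sort(unique(.data$tree_species))),
      .groups = "drop"
    )
  if (any(design$n_declared > 1)) {
    stop("plot with inconsistent plot_richness values: ",
         design$plot_id[design$n_declared > 1][1], call. = FALSE)
  }
  n_obs <- lengths(design$species)
  bad <- which(n_obs != design$richness)
  if (length(bad) > 0) {
    stop(sprintf("plot '%s' declares richness %d but %d species were observed",
                 design$plot_id[bad[1]], design$richness[bad[1]], n_obs[bad[1]]),
         call. = FALSE)
  }
  design |>
    dplyr::select(!"n_declared") |>
    dplyr::arrange(.data$richness, .data$plot_id)
}

#' Check the broken-stick structure of a plot design
#'
#' In a broken-stick design the species sets within each richness level are
#' pairwise disjoint and their union is the full species pool.
#'
#' @param design Plot design tibble from [build_design()].
#' @return The species pool (sorted character vector), invisibly usable;
#'   errors if the structure is violated.
#' @export
validate_broken_stick <- function(design) {
  pool <- sort(unique(unlist(design$species)))
  for (r in sort(unique(design$richness))) {
    sets <- design$species[design$richness == r]
    all_sp <- unlist(sets)
    if (anyDuplicated(all_sp)) {
      stop(sprintf("species '%s' occurs in two plots of richness %d",
                   all_sp[anyDuplicated(all_sp)], r), call. = FALSE)
    }
    if (!setequal(all_sp, pool)) {
      stop(sprintf("richness-%d plots do not cover the species pool", r),
           call. = FALSE)
    }
  }
  pool
}

# Kuhn's augmenting-path maximum bipartite matching.
# adj: list over left vertices of integer vectors of admissible right vertices.
# Returns integer vector match_left (0 = unmatched).
max_bipartite_matching <- function(adj, n_right) {
  match_right <- integer(n_right)           # right -> left (0 = free)
  try_augment <- function(u, seen) {
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        if (match_right[v] == 0L || Recall(match_right[v], seen)) {
          match_right[v] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (u in seq_along(adj)) {
    try_augment(u, logical(n_right))
  }
  match_left <- integer(length(adj))
  for (v in seq_len(n_right)) if (match_right[v] > 0L) match_left[match_right[v]] <- v
  match_left
}

#' Assign species to distinct high-diversity plots
#'
#' Finds a perfect matching of the given species to distinct high-diversity
#' plots that contain them. Among all perfect matchings the lexicographically
#' smallest is returned: species are processed in the order given, and each
#' takes the smallest feasible plot id that still allows the remaining
#' species to be matched (checked by augmenting-path maximum matching).
#'
#' @param species Character vector of species, one plot needed per species.
#' @param high_plots Plot design tibble restricted to high-diversity plots.
#' @return A tibble (`plot_id`, `species`), or `NULL` if no perfect matching
#'   exists.
#' @export
match_high_plots <- function(species, high_plots) {
  if (nrow(high_plots) < length(species)) return(NULL)
  plot_ids <- sort(high_plots$plot_id)
  plot_species <- high_plots$species[match(plot_ids, high_plots$plot_id)]
  admissible <- lapply(species, function(s) which(vapply(plot_species, function(ps) s %in% ps, logical(1))))
  if (any(lengths(admissible) == 0)) return(NULL)

  feasible <- function(adj_rest, n_right) {
    if (length(adj_rest) == 0) return(TRUE)
    m <- max_bipartite_matching(adj_rest, n_right)
    all(m > 0L)
  }
  if (!feasible(admissible, length(plot_ids))) return(NULL)

  used <- logical(length(plot_ids))
  assigned <- integer(length(species))
  for (i in seq_along(species)) {
    for (v in admissible[[i]]) {
      if (used[v]) next
      # tentatively fix species i -> plot v; can the rest still be matched?
      rest_idx <- if (i < length(species)) (i + 1):length(species) else integer(0)
      adj_rest <- lapply(admissible[rest_idx], function(a) setdiff(a, c(which(used), v)))
      if (all(lengths(adj_rest) > 0) && feasible(adj_rest, length(plot_ids))) {
        assigned[i] <- v
        used[v] <- TRUE
        break
      }
    }
    if (assigned[i] == 0L) return(NULL)
  }
  tibble::tibble(plot_id = plot_ids[assigned], species = species)
}

#' Enumerate balanced subsampling combinations
#'
#' Enumerates every subsampling combination of the broken-stick design: a
#' choice of k of the k+1 two-species plots together with one planted
#' species per chosen plot (k = pool size / 2 - 1; 7 for the 16-species
#' design, giving 8 x 2^7 = 1024 combinations before exclusions). For each
#' choice the monoculture cells are forced (the chosen species'
#' monocultures) and the high-diversity cells are the lexicographically
#' smallest perfect matching of the species to distinct high-diversity plots
#' ([match_high_plots()]). Choices containing an excluded species are
#' discarded, as are (rare, structurally impossible here) choices with no
#' high-level matching. Output is deterministic: combinations are sorted by
#' (chosen plot ids, chosen species) and indexed from 0.
#'
#' @param design Plot design tibble from [build_design()]; must pass
#'   [validate_broken_stick()].
#' @param excluded_species Character vector of species to exclude.
#' @return A long tibble with columns `combination_id`, `level` (MONO, TWO,
#'   HIGH), `plot_id`, `species`: one row per sampling cell, 3k rows per
#'   combination. The number of choices discarded for lack of a high-level
#'   matching is attached as attribute `n_unmatched`.
#' @export
enumerate_combinations <- function(design, excluded_species = character()) {
  pool <- validate_broken_stick(design)
  n <- length(pool)
  if (n < 8 || bitwAnd(n, n - 1L) != 0) {
    stop("species pool size must be a power of 2 and >= 8; got ", n, call. = FALSE)
  }
  k <- n %/% 2L - 1L
  bad_excl <- setdiff(excluded_species, pool)
  if (length(bad_excl) > 0) {
    stop("excluded species not in the pool: ", paste(bad_excl, collapse = ", "),
         call. = FALSE)
  }
  if (length(excluded_species) > n - k) {
    stop("cannot exclude more than ", n - k, " species", call. = FALSE)
  }

  two <- design[design$richness == 2L, ]
  two <- two[order(two$plot_id), ]
  mono <- design[design$richness == 1L, ]
  mono_plot_of <- setNames(mono$plot_id, vapply(mono$species, `[[`, character(1), 1))
  high <- design[design$richness >= 4L, ]

  plot_subsets <- utils::combn(two$plot_id, k, simplify = FALSE)
  n_unmatched <- 0L
  combos <- list()
  for (subset in plot_subsets) {
    sp_options <- lapply(subset, function(p) sort(two$species[[match(p, two$plot_id)]]))
    grid <- expand.grid(rev(sp_options), stringsAsFactors = FALSE)
    grid <- grid[, rev(seq_len(k)), drop = FALSE]  # first plot varies slowest
    for (g in seq_len(nrow(grid))) {
      species <- as.character(unlist(grid[g, ]))
      if (any(species %in% excluded_species)) next
      if (anyDuplicated(species)) next  # cannot happen in a broken-stick design
      hi <- match_high_plots(species, high)
      if (is.null(hi)) {
        n_unmatched <- n_unmatched + 1L
        next
      }
      combos[[length(combos) + 1L]] <- list(
        plot_key = paste(subset, collapse = "\t"),
        species_key = paste(species, collapse = "\t"),
        cells = tibble::tibble(
          level = rep(c("MONO", "TWO", "HIGH"), each = k),
          plot_id = c(unname(mono_plot_of[species]), subset, hi$plot_id),
          species = c(species, species, hi$species)
        )
      )
    }
  }
  if (length(combos) == 0) {
    out <- tibble::tibble(combination_id = integer(0), level = character(0),
                          plot_id = character(0), species = character(0))
    attr(out, "n_unmatched") <- n_unmatched
    return(out)
  }
  ord <- order(vapply(combos, `[[`, character(1), "plot_key"),
               vapply(combos, `[[`, character(1), "species_key"),
               method = "radix")
  out <- dplyr::bind_rows(lapply(seq_along(ord), function(i) {
    dplyr::mutate(combos[[ord[i]]]$cells, combination_id = i - 1L,
                  .before = 1L)
  }))
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Cells of one combination at one diversity level
#'
#' @param combos Long combination tibble from [enumerate_combinations()].
#' @param id Combination id.
#' @param level `"MONO"`, `"TWO"` or `"HIGH"`.
#' @return Tibble of (plot_id, species) cells.
#' @export
combination_cells <- function(combos, id, level) {
  cells <- combos[combos$combination_id == id & combos$level == level,
                  c("plot_id", "species")]
  if (nrow(cells) == 0) stop("no cells for combination ", id, " at level ", level,
                             call. = FALSE)
  cells
}
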