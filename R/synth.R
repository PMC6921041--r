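#' Generate a broken-stick planting design with sample records
#'
#' Randomly halves a pool of `n_species` tree species recursively, producing
#' nested plot communities of richness n, n/2, ..., 2, 1 (for 16 species:
#' 1 + 2 + 4 + 8 + 16 = 31 plots), and emits five sample records per
#' (plot, species) sampling cell. Optionally a few samples of one species
#' can be dropped to emulate incomplete sampling of a failing species (the
#' study design lost six samples of one species this way, giving 394 rather
#' than 400 samples).
#'
#' @param n_species Pool size; a power of 2, >= 8.
#' @param seed Integer seed; the halving and ids are deterministic given it.
#' @param drop_samples Number of samples of `drop_species` to remove.
#' @param drop_species Species whose samples are dropped (default: the last
#'   species of the pool).
#' @return A list: `design` (plot tibble as from [build_design()]),
#'   `metadata` (sample record tibble), `pool` (species names).
#' @export
generate_design <- function(n_species = 16L, seed = 1L, drop_samples = 0L,
                            drop_species = NULL) {
  n <- as.integer(n_species)
  if (n < 8 || bitwAnd(n, n - 1L) != 0) {
    stop("n_species must be a power of 2 and >= 8", call. = FALSE)
  }
  pool <- sprintf("sp%02d", seq_len(n))
  perm <- with_local_seed(seed, sample(pool))
  plots <- list()
  r <- n
  while (r >= 1L) {
    n_plots <- n %/% r
    for (i in seq_len(n_plots)) {
      plots[[length(plots) + 1L]] <- list(
        plot_id = sprintf("P%02d.%02d", r, i),
        richness = r,
        species = sort(perm[((i - 1L) * r + 1L):(i * r)])
      )
    }
    r <- r %/% 2L
  }
  design <- tibble::tibble(
    plot_id = vapply(plots, `[[`, character(1), "plot_id"),
    richness = vapply(plots, `[[`, integer(1), "richness"),
    species = lapply(plots, `[[`, "species")
  ) |> dplyr::arrange(.data$richness, .data$plot_id)

  metadata <- design |>
    dplyr::mutate(species2 = .data$species) |>
    tidyr::unnest_longer("species2", values_to = "tree_species") |>
    dplyr::select("plot_id", richness2 = "richness", "tree_species") |>
    tidyr::expand_grid(replicate = 1:5) |>
    dplyr::transmute(
      sample_id = sprintf("%s_%s_r%d", .data$plot_id, .data$tree_species,
                          .data$replicate),
      plot_id = .data$plot_id,
      tree_species = .data$tree_species,
      plot_richness = .data$richness2,
      replicate = .data$replicate
    )
  if (drop_samples > 0) {
    if (is.null(drop_species)) drop_species <- pool[n]
    cand <- metadata |>
      dplyr::filter(.data$tree_species == drop_species) |>
      dplyr::arrange(dplyr::desc(.data$replicate),
                     dplyr::desc(.data$plot_richness), .data$plot_id)
    if (drop_samples >= nrow(cand)) {
      stop("cannot drop all samples of species ", drop_species, call. = FALSE)
    }
    metadata <- metadata |>
      dplyr::filter(!.data$sample_id %in% cand$sample_id[seq_len(drop_samples)])
  }
  list(design = design, metadata = validate_sample_metadata(metadata),
       pool = pool)
}

# Default guild proportions of generated OTUs (observed community
# composition: saprotrophs dominate, ~half unassigned).
DEFAULT_GUILD_PROPS <- c(saprotroph = 0.31, ectomycorrhizal = 0.07,
                         arbuscular_mycorrhizal = 0.05, plant_pathogen = 0.05,
                         unknown = 0.46, other = 0.06)

#' Generate a synthetic OTU count table with planted structure
#'
#' Zero-inflated occurrence model: every OTU has an activity rate `p_focal`,
#' the per-sample presence probability where it thrives. Generalists thrive
#' everywhere (presence probability `p_focal` in all samples); specialists
#' thrive only in plots containing their preferred tree species and are
#' suppressed to the background rate `p_bg` elsewhere. With `p_focal ==
#' p_bg` the two groups are statistically identical (the null
#' configuration). Conditional on presence, a raw
#' abundance is drawn from a heavy-tailed discrete distribution (1 +
#' negative binomial) scaled by a lognormal per-OTU abundance parameter;
#' each sample's raw counts are then resampled multinomially to a target
#' depth drawn uniformly from `depth_range`, so the support direction of
#' the occurrence structure is preserved. Deterministic given `seed`.
#'
#' @param dsg Design list from [generate_design()].
#' @param n_otus Number of OTUs.
#' @param prop_specialist Fraction of OTUs that are specialists.
#' @param p_focal Per-sample presence probability where an OTU thrives
#'   (everywhere for generalists; plots containing the preferred species
#'   for specialists); must be >= `p_bg`.
#' @param p_bg Background presence probability of specialists outside
#'   plots with their preferred species.
#' @param depth_range Length-2 integer vector of per-sample sequencing
#'   depths (uniform draw).
#' @param guild_props Named numeric vector of guild proportions; must use
#'   the closed guild set and sum to 1.
#' @param seed Integer seed.
#' @return A list: `counts` (OTU x sample matrix), `guilds` (tibble),
#'   `truth` (per-OTU ground-truth tibble).
#' @export
generate_counts <- function(dsg, n_otus = 2000L, prop_specialist = 0.3,
                            p_focal = 0.5, p_bg = 0.05,
                            depth_range = c(700L, 3000L),
                            guild_props = DEFAULT_GUILD_PROPS, seed = 1L) {
  if (p_focal < p_bg) stop("p_focal must be >= p_bg", call. = FALSE)
  stopifnot(abs(sum(guild_props) - 1) < 1e-8,
            all(names(guild_props) %in% GUILD_LEVELS))
  metadata <- dsg$metadata
  pool <- dsg$pool
  n_samples <- nrow(metadata)
  with_local_seed(seed, {
    otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
    guild <- sample(names(guild_props), n_otus, replace = TRUE,
                    prob = guild_props)
    specialist <- runif(n_otus) < prop_specialist
    preferred <- ifelse(specialist, sample(pool, n_otus, replace = TRUE),
                        NA_character_)
    scale <- stats::rlnorm(n_otus, meanlog = 1.5, sdlog = 1)

    # sample x species-present lookup
    plot_species <- dsg$design$species[match(metadata$plot_id, dsg$design$plot_id)]
    counts <- matrix(0L, nrow = n_otus, ncol = n_samples,
                     dimnames = list(otu_ids, metadata$sample_id))
    pref_idx <- match(preferred, pool)
    # presence probability matrix built per sample to keep memory modest
    for (j in seq_len(n_samples)) {
      in_plot <- pool %in% plot_species[[j]]
      suppressed <- specialist & !in_plot[pref_idx]
      p <- ifelse(suppressed, p_bg, p_focal)
      pres <- runif(n_otus) < p
      if (!any(pres)) next
      raw <- numeric(n_otus)
      raw[pres] <- 1 + stats::rnbinom(sum(pres), size = 1, mu = scale[pres])
      depth <- sample(seq(depth_range[1], depth_range[2]), 1)
      counts[, j] <- as.integer(stats::rmultinom(1, depth, prob = raw))
    }
    truth <- tibble::tibble(
      otu_id = otu_ids, guild = guild, specialist = specialist,
      preferred_species = preferred,
      p_focal = p_focal,
      p_bg = ifelse(specialist, p_bg, p_focal),
      abundance_scale = scale
    )
    list(counts = validate_count_table(counts),
         guilds = tibble::tibble(otu_id = otu_ids, guild = guild),
         truth = truth)
  })
}

#' Bundled synthetic fixtures
#'
#' Reproducible named datasets: `"tiny"` (8 species, 15 plots, 200 OTUs;
#' fast tests), `"paperlike"` (16 species, 31 plots, 394 samples, 2000
#' OTUs; one species excluded from the subsampling, emulating the study
#' conditions), and `"null"` (like tiny but with no planted specialists).
#'
#' @param name Fixture name: `"tiny"`, `"paperlike"` or `"null"`.
#' @param seed Integer seed (default 1).
#' @param n_otus Override the preset's OTU count (e.g. to speed up
#'   simulation studies); `NULL` keeps the preset default.
#' @return A list: `counts`, `metadata`, `design`, `guilds`, `truth`,
#'   `excluded_species` (species to exclude from combination enumeration,
#'   possibly empty), `pool`.
#' @export
make_fixture <- function(name, seed = 1L, n_otus = NULL) {
  registry <- c("tiny", "paperlike", "null")
  if (!name %in% registry) {
    stop("unknown fixture '", name, "'; available: ",
         paste(registry, collapse = ", "), call. = FALSE)
  }
  cfg <- switch(name,
    tiny = list(n_species = 8L, n_otus = 200L, drop_samples = 0L,
                prop_specialist = 0.3, p_focal = 0.5, p_bg = 0.05,
                excluded = character(0)),
    paperlike = list(n_species = 16L, n_otus = 2000L, drop_samples = 6L,
                     prop_specialist = 0.3, p_focal = 0.5, p_bg = 0.05,
                     excluded = "sp16"),
    null = list(n_species = 8L, n_otus = 200L, drop_samples = 0L,
                prop_specialist = 0.3, p_focal = 0.05, p_bg = 0.05,
                excluded = character(0))
  )
  if (!is.null(n_otus)) cfg$n_otus <- as.integer(n_otus)
  dsg <- generate_design(cfg$n_species, seed = seed,
                         drop_samples = cfg$drop_samples)
  gen <- generate_counts(dsg, n_otus = cfg$n_otus,
                         prop_specialist = cfg$prop_specialist,
                         p_focal = cfg$p_focal, p_bg = cfg$p_bg,
                         seed = seed + 1L)
  list(counts = gen$counts, metadata = dsg$metadata, design = dsg$design,
       guilds = gen$guilds, truth = gen$truth,
       excluded_species = cfg$excluded, pool = dsg$pool)
}
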