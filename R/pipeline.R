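#' Run the full co-occurrence and specialization analysis
#'
#' Orchestrates the pipeline end-to-end: input loading (files or a
#' synthetic preset), preprocessing, combination enumeration, per-
#' combination webs and network metrics at each link threshold,
#' Kruskal-Wallis contrasts between diversity levels, fixed-margin null
#' model NODF comparison, phi specialization (per-combination medians,
#' guild contrasts, top specialists, frequent OTUs), and writes the result
#' tables plus a JSON run manifest to `out_dir`.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Recognized keys (all optional unless noted):
#'   * `inputs`: `counts`, `metadata`, `guilds` file paths - or `synth`:
#'     `preset`, `seed`, `n_otus` for a generated dataset (one of the two
#'     is required);
#'   * `preprocess`: `depth` (700), `min_reads` (10), `max_total` (3),
#'     `seed` (1);
#'   * `design`: `exclude` (character vector of species);
#'   * `networks`: `thresholds` (1:5), `modularity_restarts` (20),
#'     `seed` (1), `max_combinations` (cap on combinations analysed;
#'     default all);
#'   * `nullmodel`: `reps` (1), `seed` (1), `threshold` (3);
#'   * `phi`: `presence_min` (1);
#'   * `stats`: `correction` ("holm"), `alpha` (0.05).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest. Side effect: writes metrics.tsv, medians.tsv, kw_tests.tsv,
#'   nodf_null.tsv, phi.tsv, phi_medians.tsv, guild_phi.tsv,
#'   specialists.tsv, frequent.tsv and manifest.json in `out_dir`.
#' @export
run_full_analysis <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- function(path, default) {
    x <- config
    for (k in path) {
      if (is.null(x[[k]])) return(default)
      x <- x[[k]]
    }
    x
  }
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit({
    if (!ok && length(written) > 0) unlink(written)
  })
  emit <- function(x, file) {
    path <- file.path(out_dir, file)
    write_table(x, path)
    written <<- c(written, path)
    path
  }

  # ---- inputs ----
  if (!is.null(config$synth)) {
    preset <- cfg(c("synth", "preset"), "tiny")
    synth_seed <- cfg(c("synth", "seed"), 1L)
    fx <- make_fixture(preset, seed = synth_seed,
                       n_otus = cfg(c("synth", "n_otus"), NULL))
    counts <- fx$counts
    metadata <- fx$metadata
    guilds <- fx$guilds
    exclude <- cfg(c("design", "exclude"), fx$excluded_species)
  } else if (!is.null(config$inputs)) {
    counts <- read_count_table(config$inputs$counts)
    metadata <- read_sample_metadata(config$inputs$metadata)
    guilds <- if (!is.null(config$inputs$guilds)) {
      read_guild_map(config$inputs$guilds)
    } else tibble::tibble(otu_id = character(0), guild = character(0))
    exclude <- cfg(c("design", "exclude"), character(0))
  } else {
    stop("config needs either 'inputs' or 'synth'", call. = FALSE)
  }

  # ---- preprocess ----
  pp_seed <- cfg(c("preprocess", "seed"), 1L)
  say("preprocessing ", ncol(counts), " samples, ", nrow(counts), " OTUs")
  pp <- preprocess_counts(counts,
                          max_total = cfg(c("preprocess", "max_total"), 3L),
                          depth = cfg(c("preprocess", "depth"), 700L),
                          min_reads = cfg(c("preprocess", "min_reads"), 10L),
                          seed = pp_seed)
  metadata <- metadata[metadata$sample_id %in% pp$samples, ]

  # ---- design / combinations ----
  design <- build_design(metadata)
  combos <- enumerate_combinations(design, excluded_species = exclude)
  ids <- unique(combos$combination_id)
  max_comb <- cfg(c("networks", "max_combinations"), NULL)
  if (!is.null(max_comb) && length(ids) > max_comb) ids <- ids[seq_len(max_comb)]
  say(length(ids), " subsampling combinations")

  thresholds <- as.integer(cfg(c("networks", "thresholds"), 1:5))
  restarts <- cfg(c("networks", "modularity_restarts"), 20L)
  net_seed <- cfg(c("networks", "seed"), 1L)
  presence_min <- cfg(c("phi", "presence_min"), 1L)

  # ---- per-combination webs, metrics, phi ----
  metric_rows <- list()
  phi_rows <- list()
  phi_median_rows <- list()
  failed <- NULL
  for (id in ids) {
    res <- tryCatch({
      for (lv in DIVERSITY_CLASSES) {
        cells <- combination_cells(combos, id, lv)
        for (t in thresholds) {
          web <- build_web(pp$incidence, cells, metadata, threshold = t)
          nm <- network_metrics(web, counts = pp$rarefied, cells = cells,
                                metadata = metadata,
                                seed = net_seed + id, restarts = restarts)
          metric_rows[[length(metric_rows) + 1L]] <-
            dplyr::mutate(nm, combination_id = id, level = lv, threshold = t,
                          .before = 1L)
        }
        ph <- phi_table(pp$incidence, cells, metadata,
                        presence_min = presence_min)
        phi_rows[[length(phi_rows) + 1L]] <-
          dplyr::mutate(ph, combination_id = id, level = lv, .before = 1L)
        phi_median_rows[[length(phi_median_rows) + 1L]] <- tibble::tibble(
          combination_id = id, level = lv,
          median_positive_phi = median_positive_phi(ph$phi))
      }
      NULL
    }, error = function(e) e)
    if (!is.null(res)) {
      stop("combination ", id, " failed: ", conditionMessage(res), call. = FALSE)
    }
    if (!quiet && (id + 1) %% 50 == 0) say("  ... combination ", id)
  }
  metrics <- dplyr::bind_rows(metric_rows) |>
    tidyr::pivot_longer(cols = !c("combination_id", "level", "threshold"),
                        names_to = "metric", values_to = "value")
  emit(metrics, "metrics.tsv")

  medians <- metrics |>
    dplyr::group_by(.data$level, .data$threshold, .data$metric) |>
    dplyr::summarise(median = median(.data$value, na.rm = TRUE), .groups = "drop")
  emit(medians, "medians.tsv")

  # ---- KW contrasts between diversity levels ----
  alpha <- cfg(c("stats", "alpha"), 0.05)
  correction <- cfg(c("stats", "correction"), "holm")
  kw_rows <- list()
  add_kw <- function(groups, metric, threshold) {
    kw <- kruskal_wallis(groups)
    ph <- kruskal_posthoc(groups, alpha = alpha, correction = correction)
    kw_rows[[length(kw_rows) + 1L]] <<- tibble::tibble(
      threshold = threshold, metric = metric, test = "kruskal",
      group1 = NA_character_, group2 = NA_character_,
      statistic = kw$statistic, df = kw$df, p_value = kw$p.value,
      critical_diff = NA_real_, significant = kw$p.value < alpha)
    kw_rows[[length(kw_rows) + 1L]] <<- tibble::tibble(
      threshold = threshold, metric = metric, test = "posthoc",
      group1 = ph$group1, group2 = ph$group2, statistic = ph$diff,
      df = NA_integer_, p_value = NA_real_,
      critical_diff = ph$critical_diff, significant = ph$significant)
  }
  for (t in thresholds) {
    for (met in unique(metrics$metric)) {
      sub <- metrics[metrics$threshold == t & metrics$metric == met &
                       !is.na(metrics$value), ]
      groups <- split(sub$value, sub$level)
      groups <- groups[lengths(groups) > 0]
      if (length(groups) >= 2) add_kw(groups, met, t)
    }
  }

  # ---- null model NODF ----
  null_reps <- cfg(c("nullmodel", "reps"), 1L)
  null_seed <- cfg(c("nullmodel", "seed"), 1L)
  null_threshold <- cfg(c("nullmodel", "threshold"), 3L)
  say("null model: ", null_reps, " replicate(s)")
  obs_nodf <- metrics |>
    dplyr::filter(.data$metric == "nodf", .data$threshold == null_threshold)
  null_rows <- list()
  for (rep in seq_len(null_reps)) {
    shuffled <- patefield_shuffle(pp$rarefied, seed = null_seed + rep)
    null_inc <- to_incidence(shuffled)
    for (id in ids) {
      for (lv in DIVERSITY_CLASSES) {
        cells <- combination_cells(combos, id, lv)
        web <- build_web(null_inc, cells, metadata, threshold = null_threshold)
        null_rows[[length(null_rows) + 1L]] <- tibble::tibble(
          rep = rep, combination_id = id, level = lv,
          nodf = if (nrow(web) >= 2 && ncol(web) >= 2) nodf(web) else NA_real_)
      }
    }
  }
  null_nodf <- dplyr::bind_rows(null_rows)
  nodf_tbl <- dplyr::bind_rows(lapply(as.character(DIVERSITY_CLASSES), function(lv) {
    obs <- obs_nodf$value[obs_nodf$level == lv & !is.na(obs_nodf$value)]
    nul <- null_nodf$nodf[null_nodf$level == lv & !is.na(null_nodf$nodf)]
    if (length(obs) == 0 || length(nul) == 0) {
      return(tibble::tibble(level = lv, obs_median = NA_real_,
                            null_median = NA_real_, p_value = NA_real_))
    }
    dplyr::mutate(null_nodf_comparison(obs, nul), level = lv, .before = 1L)
  }))
  emit(nodf_tbl, "nodf_null.tsv")

  # ---- specialization ----
  phi_records <- dplyr::bind_rows(phi_rows)
  emit(phi_records, "phi.tsv")
  emit(dplyr::bind_rows(phi_median_rows), "phi_medians.tsv")

  phi_level_groups <- dplyr::bind_rows(phi_median_rows) |>
    dplyr::filter(!is.na(.data$median_positive_phi))
  if (length(unique(phi_level_groups$level)) >= 2) {
    add_kw(split(phi_level_groups$median_positive_phi, phi_level_groups$level),
           "median_positive_phi", NA_integer_)
  }

  guild_tbl <- tryCatch(
    group_phi_comparison(phi_records, guilds, alpha = alpha),
    error = function(e) NULL)
  if (!is.null(guild_tbl)) {
    emit(guild_tbl$group_medians, "guild_phi.tsv")
    kw_rows[[length(kw_rows) + 1L]] <- tibble::tibble(
      threshold = NA_integer_, metric = "phi_by_guild", test = "kruskal",
      group1 = NA_character_, group2 = NA_character_,
      statistic = guild_tbl$kruskal$statistic, df = guild_tbl$kruskal$df,
      p_value = guild_tbl$kruskal$p.value, critical_diff = NA_real_,
      significant = guild_tbl$kruskal$p.value < alpha)
    kw_rows[[length(kw_rows) + 1L]] <- tibble::tibble(
      threshold = NA_integer_, metric = "phi_by_guild", test = "posthoc",
      group1 = guild_tbl$posthoc$group1, group2 = guild_tbl$posthoc$group2,
      statistic = guild_tbl$posthoc$diff, df = NA_integer_,
      p_value = NA_real_, critical_diff = guild_tbl$posthoc$critical_diff,
      significant = guild_tbl$posthoc$significant)
  } else {
    emit(tibble::tibble(guild = character(0), n = integer(0),
                        median_phi = numeric(0)), "guild_phi.tsv")
  }
  emit(dplyr::bind_rows(kw_rows), "kw_tests.tsv")

  spec <- rank_specialists(phi_records, top_n = cfg(c("phi", "top_n"), 200L))
  spec_tbl <- tibble::as_tibble(spec$matrix, rownames = "otu_id")
  emit(spec_tbl, "specialists.tsv")

  sub_combos <- combos[combos$combination_id %in% ids, ]
  freq <- frequent_otus(pp$incidence, sub_combos, metadata,
                        presence_min = presence_min)
  emit(freq$flags, "frequent.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("treeweb")),
    seeds = list(preprocess = pp_seed, networks = net_seed,
                 nullmodel = null_seed,
                 synth = if (!is.null(config$synth)) cfg(c("synth", "seed"), 1L)),
    n_combinations = length(ids),
    n_unmatched = attr(combos, "n_unmatched"),
    thresholds = thresholds,
    n_otus_preprocessed = nrow(pp$rarefied),
    n_samples = length(pp$samples),
    rows = list(metrics = nrow(metrics), phi = nrow(phi_records),
                medians = nrow(medians)),
    excluded_species = as.character(exclude)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  written <- c(written, manifest_path)
  ok <- TRUE
  say("done: ", length(written), " files in ", out_dir)
  invisible(list(metrics = metrics, medians = medians,
                 phi_medians = dplyr::bind_rows(phi_median_rows),
                 nodf_null = nodf_tbl, frequent = freq,
                 specialists = spec, manifest = manifest))
}
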