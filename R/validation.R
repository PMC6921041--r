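#' Parameter-recovery experiment for phi specialization
#'
#' Validates that the phi analysis recovers planted specialization: over
#' `n_seeds` independently generated communities on a fixed 16-species
#' broken-stick design, compares the median positive phi of planted
#' specialist OTUs against generalist OTUs in monoculture-level networks.
#' The planting design is held fixed (as in a real experiment) and one
#' species is excluded from the subsampling, mirroring the study
#' conditions; only the community generation varies with the seed.
#'
#' @param n_seeds Number of generated communities.
#' @param n_otus OTUs per community.
#' @param p_focal,p_bg Generator occurrence rates (see [generate_counts()]);
#'   `p_focal == p_bg` gives the null (no enrichment) configuration.
#' @param n_combos Subsampling combinations evaluated per community.
#' @param seed Master seed; community seeds are derived from it.
#' @param level Diversity level analysed (default `"MONO"`).
#' @return A tibble with one row per seed: `seed`, `specialist_median`,
#'   `generalist_median`, `n_specialist_records`, `n_generalist_records`.
#' @export
phi_recovery_experiment <- function(n_seeds = 50L, n_otus = 300L,
                                    p_focal = 0.5, p_bg = 0.05,
                                    n_combos = 5L, seed = 1L,
                                    level = "MONO") {
  dsg <- generate_design(16L, seed = seed)
  combos <- enumerate_combinations(dsg$design,
                                   excluded_species = dsg$pool[16])
  ids <- unique(combos$combination_id)[seq_len(n_combos)]
  cell_list <- lapply(ids, function(id) combination_cells(combos, id, level))
  rows <- lapply(seq_len(n_seeds), function(i) {
    gen <- generate_counts(dsg, n_otus = n_otus, p_focal = p_focal,
                           p_bg = p_bg, seed = seed + 1000L * i)
    pp <- preprocess_counts(gen$counts, seed = seed + 1000L * i + 1L)
    md <- dsg$metadata[dsg$metadata$sample_id %in% pp$samples, ]
    recs <- dplyr::bind_rows(lapply(cell_list, function(cells) {
      phi_table(pp$incidence, cells, md)
    }))
    is_spec <- gen$truth$specialist[match(recs$otu_id, gen$truth$otu_id)]
    pos <- !is.na(recs$phi) & recs$phi > 0
    tibble::tibble(
      seed = seed + 1000L * i,
      specialist_median = median(recs$phi[pos & is_spec]),
      generalist_median = median(recs$phi[pos & !is_spec]),
      n_specialist_records = sum(pos & is_spec),
      n_generalist_records = sum(pos & !is_spec)
    )
  })
  dplyr::bind_rows(rows)
}
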