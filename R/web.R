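# Sample ids of one (plot, species) sampling cell, checked against the
# available columns of the (incidence or count) table.
cell_sample_ids <- function(metadata, plot_id, species, available,
                            n_required = 5L) {
  ids <- metadata$sample_id[metadata$plot_id == plot_id &
                              metadata$tree_species == species]
  ids <- ids[ids %in% available]
  if (length(ids) != n_required) {
    stop(sprintf("cell (plot '%s', species '%s') has %d sample(s), expected %d",
                 plot_id, species, length(ids), n_required), call. = FALSE)
  }
  ids
}

#' Build a tree-fungal co-occurrence web
#'
#' Links tree species to fungal OTUs by co-occurrence: a link is drawn when
#' the OTU is present in at least `threshold` of the five soil samples of
#' that tree species' sampling cell. OTUs with no link are dropped from the
#' web; the remaining column order follows the input OTU order.
#'
#' @param incidence Binary incidence matrix (OTUs x samples).
#' @param cells Tibble of (plot_id, species) sampling cells — one diversity
#'   level of one combination, see [combination_cells()].
#' @param metadata Sample metadata tibble.
#' @param threshold Link threshold t in 1..5: minimum number of the five
#'   samples in which the OTU must occur.
#' @return A binary matrix with tree species as rows and OTUs as columns,
#'   class `tw_web`, with the threshold attached as attribute `threshold`.
#' @export
build_web <- function(incidence, cells, metadata, threshold = 3L) {
  if (!threshold %in% 1:5) stop("threshold must be in 1..5", call. = FALSE)
  pres <- matrix(0L, nrow = nrow(cells), ncol = nrow(incidence),
                 dimnames = list(cells$species, rownames(incidence)))
  for (i in seq_len(nrow(cells))) {
    ids <- cell_sample_ids(metadata, cells$plot_id[i], cells$species[i],
                           colnames(incidence))
    pres[i, ] <- as.integer(rowSums(incidence[, ids, drop = FALSE]) >= threshold)
  }
  web <- pres[, colSums(pres) > 0, drop = FALSE]
  attr(web, "threshold") <- as.integer(threshold)
  class(web) <- c("tw_web", class(web))
  web
}

check_web <- function(web, min_rows = 1L, min_cols = 1L) {
  if (!is.matrix(web) || nrow(web) < min_rows || ncol(web) < min_cols) {
    stop(sprintf("web must be a matrix with >= %d row(s) and >= %d column(s)",
                 min_rows, min_cols), call. = FALSE)
  }
  invisible(web)
}

#' Network connectance
#'
#' The realized proportion of possible links: L / (I x J) for a web with L
#' links, I tree species and J OTUs.
#'
#' @param web Binary web matrix (trees x OTUs).
#' @return Connectance in \[0, 1\].
#' @export
connectance <- function(web) {
  check_web(web)
  sum(web) / (nrow(web) * ncol(web))
}

#' Fungal generality
#'
#' Mean effective number of tree partners per fungal OTU, link-weighted
#' (Bersier-type): for a binary web the effective partner number of an OTU
#' is its degree d, so generality = sum(d^2) / L. Ranges from 1 (every OTU
#' on a single tree) to the number of tree species (complete web).
#'
#' @param web Binary web matrix (trees x OTUs).
#' @return Generality (effective species count).
#' @export
generality <- function(web) {
  check_web(web)
  d <- colSums(web)
  L <- sum(d)
  if (L == 0) stop("web has no links", call. = FALSE)
  sum(d^2) / L
}

#' Fungal C score
#'
#' Mean normalized checkerboard units over all unordered OTU pairs
#' (Stone-Roberts): for OTUs f, g with degrees r_f, r_g sharing S trees, the
#' pair contributes (r_f - S)(r_g - S) / (r_f r_g). Values near 1 indicate
#' segregation (disaggregation), near 0 aggregation.
#'
#' @param web Binary web matrix (trees x OTUs).
#' @return C score in \[0, 1\].
#' @export
c_score <- function(web) {
  check_web(web, min_cols = 2L)
  r <- colSums(web)
  J <- ncol(web)
  S <- crossprod(web)                       # shared trees per OTU pair
  rf <- matrix(r, J, J)                     # r_f down rows
  cb <- (rf - S) * (t(rf) - S)              # checkerboard units
  norm <- cb / (rf * t(rf))
  mean(norm[upper.tri(norm)])
}

#' NODF nestedness
#'
#' Nestedness metric based on Overlap and Decreasing Fill (Almeida-Neto et
#' al.): rows and columns are sorted by decreasing marginal totals; every
#' ordered pair where the later row (column) has a strictly smaller total
#' contributes 100 x overlap / (total of the later one), ties contribute 0;
#' NODF is the mean over all row pairs and column pairs. 0 = non-nested,
#' 100 = perfectly nested.
#'
#' @param web Binary web matrix.
#' @return NODF in \[0, 100\].
#' @export
nodf <- function(web) {
  check_web(web, min_rows = 2L, min_cols = 2L)
  pair_contributions <- function(m) {
    tot <- rowSums(m)
    ord <- order(tot, decreasing = TRUE)
    m <- m[ord, , drop = FALSE]
    tot <- tot[ord]
    n <- nrow(m)
    O <- tcrossprod(m)                      # pairwise overlap
    tot_u <- matrix(tot, n, n)              # total of the earlier (row) member
    tot_v <- t(tot_u)                       # total of the later (column) member
    contrib <- ifelse(tot_v < tot_u & tot_v > 0, 100 * O / pmax(tot_v, 1), 0)
    contrib[upper.tri(contrib)]
  }
  mean(c(pair_contributions(web), pair_contributions(t(web))))
}

#' Mean number of shared fungal partners
#'
#' Mean over unordered tree pairs of the number of OTUs linked to both.
#'
#' @param web Binary web matrix (trees x OTUs).
#' @return Non-negative real.
#' @export
mean_shared_partners <- function(web) {
  check_web(web, min_rows = 2L)
  S <- tcrossprod(web)
  mean(S[upper.tri(S)])
}

#' Pooled alpha diversity of a combination level
#'
#' Pools rarefied counts across all samples of the level's sampling cells
#' (7 plots x 5 samples in the full design) and computes OTU richness and
#' Shannon diversity (natural log).
#'
#' @param counts Rarefied count matrix (OTUs x samples).
#' @param cells Tibble of (plot_id, species) cells.
#' @param metadata Sample metadata tibble.
#' @return A list with `richness` (integer) and `shannon` (nats).
#' @export
alpha_diversity <- function(counts, cells, metadata) {
  ids <- unlist(lapply(seq_len(nrow(cells)), function(i) {
    cell_sample_ids(metadata, cells$plot_id[i], cells$species[i], colnames(counts))
  }))
  pooled <- rowSums(counts[, ids, drop = FALSE])
  pooled <- pooled[pooled > 0]
  p <- pooled / sum(pooled)
  list(richness = length(pooled), shannon = -sum(p * log(p)))
}

#' All network metrics of one web
#'
#' Computes the full per-web statistics set: OTU count, connectance,
#' generality, C score, NODF, Barber modularity (+ module count), and mean
#' shared partners; optionally pooled richness and Shannon diversity when a
#' rarefied count table is supplied.
#'
#' @param web Binary web matrix from [build_web()].
#' @param counts Optional rarefied count matrix for alpha diversity.
#' @param cells,metadata Required with `counts`: the cells the web was built
#'   from and the sample metadata.
#' @param seed Seed for the modularity optimizer.
#' @param restarts Modularity optimizer restarts.
#' @return A one-row tibble of metrics.
#' @export
network_metrics <- function(web, counts = NULL, cells = NULL, metadata = NULL,
                            seed = 1L, restarts = 20L) {
  if (ncol(web) == 0) {
    out <- tibble::tibble(n_otus = 0L, connectance = NA_real_,
                          generality = NA_real_, c_score = NA_real_,
                          nodf = NA_real_, modularity_q = NA_real_,
                          n_modules = NA_integer_,
                          mean_shared_partners = NA_real_)
  } else {
    mod <- modularity(web, seed = seed, restarts = restarts)
    out <- tibble::tibble(
      n_otus = ncol(web),
      connectance = connectance(web),
      generality = generality(web),
      c_score = if (ncol(web) >= 2) c_score(web) else NA_real_,
      nodf = if (nrow(web) >= 2 && ncol(web) >= 2) nodf(web) else NA_real_,
      modularity_q = mod$q,
      n_modules = mod$n_modules,
      mean_shared_partners = if (nrow(web) >= 2) mean_shared_partners(web) else NA_real_
    )
  }
  if (!is.null(counts)) {
    ad <- alpha_diversity(counts, cells, metadata)
    out$richness <- ad$richness
    out$shannon <- ad$shannon
  }
  out
}
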