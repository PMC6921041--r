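#' Remove rare OTUs
#'
#' Drops OTUs whose total count across all samples is at or below
#' `max_total`. With the default of 3 this discards singleton, doubleton and
#' tripleton sequences; it is applied to the raw table, before rarefaction.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param max_total OTUs with total count `<= max_total` are removed.
#' @return The filtered count matrix; the sample set is unchanged.
#' @export
drop_rare_otus <- function(counts, max_total = 3L) {
  counts <- validate_count_table(counts)
  keep <- rowSums(counts) > max_total
  counts[keep, , drop = FALSE]
}

# Stable per-sample RNG stream: a small polynomial hash of the sample id
# folded into the global seed, so rarefaction of a sample does not depend on
# the order of columns in the table.
sample_seed <- function(seed, sample_id) {
  h <- 0
  for (k in utf8ToInt(sample_id)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Rarefy samples to a common depth
#'
#' Each sample is subsampled to exactly `depth` reads, uniformly without
#' replacement (multivariate hypergeometric). Samples with fewer than `depth`
#' reads are dropped with a warning (or kept unrarefied if
#' `keep_shallow = TRUE`). The draw is deterministic given `seed`; each
#' sample uses its own stream derived from the sample id, so results do not
#' depend on column order.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param depth Target reads per sample (default 700).
#' @param seed Integer seed.
#' @param keep_shallow Keep under-depth samples unrarefied instead of
#'   dropping them.
#' @return Rarefied count matrix; every retained column sums to `depth`
#'   (unless kept shallow).
#' @export
rarefy <- function(counts, depth = 700L, seed = 1L, keep_shallow = FALSE) {
  counts <- validate_count_table(counts)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  totals <- colSums(counts)
  shallow <- totals < depth
  if (all(shallow) && !keep_shallow) {
    stop("all samples have fewer than ", depth, " reads", call. = FALSE)
  }
  if (any(shallow)) {
    msg <- paste0(sum(shallow), " sample(s) below depth ", depth,
                  if (keep_shallow) " kept unrarefied: " else " dropped: ",
                  paste(head(colnames(counts)[shallow], 5), collapse = ", "))
    warning(msg, call. = FALSE)
    if (!keep_shallow) counts <- counts[, !shallow, drop = FALSE]
  }
  out <- counts
  col_totals <- colSums(out)
  for (j in seq_len(ncol(out))) {
    if (col_totals[j] <= depth) next
    col <- out[, j]
    reads <- rep.int(seq_along(col), col)
    local_seed <- sample_seed(seed, colnames(out)[j])
    drawn <- withr_seed_sample(reads, depth, local_seed)
    out[, j] <- tabulate(drawn, nbins = length(col))
  }
  storage.mode(out) <- "integer"
  out
}

# sample() under a temporary seed without disturbing the caller's RNG state.
withr_seed_sample <- function(x, size, seed) {
  with_local_seed(seed, sample(x, size))
}

#' Prune low-abundance OTUs
#'
#' Removes OTUs with fewer than `min_reads` reads in the total (rarefied)
#' dataset. Applied after [rarefy()].
#'
#' @param counts Count matrix (OTUs x samples).
#' @param min_reads Minimum total reads for an OTU to be retained (default 10).
#' @return Filtered count matrix.
#' @export
prune_low_abundance <- function(counts, min_reads = 10L) {
  counts <- validate_count_table(counts)
  counts[rowSums(counts) >= min_reads, , drop = FALSE]
}

#' Transform counts to incidence (presence/absence)
#'
#' @param counts Count matrix.
#' @return Binary matrix of the same shape: 1 where the count is positive.
#' @export
to_incidence <- function(counts) {
  counts <- validate_count_table(counts)
  out <- (counts > 0L) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Run the full preprocessing chain
#'
#' Fixed order: rare-OTU removal on the raw table, rarefaction to `depth`,
#' low-abundance pruning on the rarefied table, incidence transform.
#'
#' @inheritParams rarefy
#' @param max_total Passed to [drop_rare_otus()].
#' @param min_reads Passed to [prune_low_abundance()].
#' @return A list with elements `rarefied` (count matrix) and `incidence`
#'   (binary matrix), plus the retained sample ids.
#' @export
preprocess_counts <- function(counts, max_total = 3L, depth = 700L,
                              min_reads = 10L, seed = 1L,
                              keep_shallow = FALSE) {
  counts <- drop_rare_otus(counts, max_total = max_total)
  rarefied <- rarefy(counts, depth = depth, seed = seed,
                     keep_shallow = keep_shallow)
  rarefied <- prune_low_abundance(rarefied, min_reads = min_reads)
  list(rarefied = rarefied,
       incidence = to_incidence(rarefied),
       samples = colnames(rarefied))
}
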