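#' Fixed-margin shuffle of a count table (Patefield algorithm)
#'
#' Draws a random contingency table with exactly the input's row and column
#' sums from the uniform-multinomial distribution (Patefield 1981), via base
#' R's `r2dtable`. The shuffle is applied to the full post-preprocessing
#' table before it is split into diversity-level subsets, so the identical
#' downstream pipeline can be re-run on the null table.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A shuffled count matrix with identical dimnames and margins.
#' @export
patefield_shuffle <- function(counts, seed = 1L) {
  counts <- validate_count_table(counts)
  if (nrow(counts) == 1 || ncol(counts) == 1) return(counts)  # forced by margins
  out <- with_local_seed(seed,
                         r2dtable(1, rowSums(counts), colSums(counts))[[1]])
  dimnames(out) <- dimnames(counts)
  storage.mode(out) <- "integer"
  out
}

#' Observed-vs-null NODF comparison
#'
#' Compares the distribution of observed NODF values (across subsampling
#' combinations) with NODF values from fixed-margin null tables: medians of
#' both plus a two-sided two-sample Wilcoxon rank-sum p-value.
#'
#' @param observed_nodf Numeric vector of observed NODF values.
#' @param null_nodf Numeric vector of null-model NODF values.
#' @return A one-row tibble: `obs_median`, `null_median`, `p_value`.
#' @export
null_nodf_comparison <- function(observed_nodf, null_nodf) {
  if (length(observed_nodf) == 0 || length(null_nodf) == 0) {
    stop("both NODF vectors must be nonempty", call. = FALSE)
  }
  w <- wilcoxon_ranksum(observed_nodf, null_nodf)
  tibble::tibble(obs_median = median(observed_nodf),
                 null_median = median(null_nodf),
                 p_value = w$p.value)
}
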