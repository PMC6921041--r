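# Independent brute-force oracles and shared fixtures for the test suite.

# Random binary web with no all-zero column and at least one link.
random_web <- function(I, J, fill = NULL) {
  if (is.null(fill)) fill <- runif(1, 0.2, 0.8)
  repeat {
    m <- matrix(rbinom(I * J, 1, fill), I, J)
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) >= 2 && sum(m) >= 1) return(m)
  }
}

bf_connectance <- function(web) {
  links <- 0
  for (i in seq_len(nrow(web))) for (j in seq_len(ncol(web))) {
    if (web[i, j] == 1) links <- links + 1
  }
  links / (nrow(web) * ncol(web))
}

bf_generality <- function(web) {
  # link-weighted mean of per-OTU effective partner counts, naive loop
  total <- 0
  L <- 0
  for (f in seq_len(ncol(web))) {
    d <- sum(web[, f])
    total <- total + d * d
    L <- L + d
  }
  total / L
}

bf_cscore <- function(web) {
  J <- ncol(web)
  vals <- c()
  for (f in seq_len(J - 1)) for (g in (f + 1):J) {
    rf <- sum(web[, f]); rg <- sum(web[, g])
    S <- sum(web[, f] == 1 & web[, g] == 1)
    vals <- c(vals, (rf - S) * (rg - S) / (rf * rg))
  }
  mean(vals)
}

bf_shared_partners <- function(web) {
  I <- nrow(web)
  vals <- c()
  for (i in seq_len(I - 1)) for (j in (i + 1):I) {
    vals <- c(vals, sum(web[i, ] == 1 & web[j, ] == 1))
  }
  mean(vals)
}

# All set partitions of n elements as restricted-growth strings.
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (m in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, m)
  }
  out
}

# Exact Barber modularity optimum: enumerate row partitions; given the rows,
# each column independently joins its best module (or stays alone at 0).
bf_modularity_opt <- function(web) {
  L <- sum(web)
  k <- rowSums(web)
  d <- colSums(web)
  best <- -Inf
  for (p in set_partitions(nrow(web))) {
    q <- 0
    for (f in seq_len(ncol(web))) {
      contribs <- vapply(unique(p), function(mm) {
        rs <- p == mm
        sum(web[rs, f]) / L - sum(k[rs]) * d[f] / L^2
      }, numeric(1))
      q <- q + max(0, max(contribs))
    }
    best <- max(best, q)
  }
  best
}

# m disjoint complete blocks of size r x c: Q = 1 - 1/m.
block_web <- function(m, r = 2L, c = 2L) {
  web <- matrix(0L, m * r, m * c)
  for (i in seq_len(m)) {
    web[(i - 1) * r + seq_len(r), (i - 1) * c + seq_len(c)] <- 1L
  }
  web
}

# Small cached fixtures (built once per test run).
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, seed = 1L, n_otus = NULL) {
  key <- paste(name, seed, n_otus %||% "default", sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture(name, seed = seed, n_otus = n_otus)
  }
  .fixture_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random valid count table with unique labels.
random_count_table <- function(n_otus, n_samples, max_count = 50L) {
  m <- matrix(sample(0:max_count, n_otus * n_samples, replace = TRUE),
              n_otus, n_samples,
              dimnames = list(sprintf("OTU%03d", seq_len(n_otus)),
                              sprintf("S%03d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}
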