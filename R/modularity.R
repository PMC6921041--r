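# Barber bipartite modularity of a partition.
# Q = sum_m ( e_m / L - a_m * b_m / L^2 ) with e_m the links inside module m,
# a_m the summed row (tree) degrees and b_m the summed column (OTU) degrees.
barber_q <- function(web, row_labels, col_labels) {
  L <- sum(web)
  k <- rowSums(web)
  d <- colSums(web)
  labs <- union(unique(row_labels), unique(col_labels))
  Er <- outer(row_labels, labs, "==") * 1
  Ec <- outer(col_labels, labs, "==") * 1
  e <- colSums((web %*% Ec) * Er)       # within-module links per module
  a <- as.numeric(k %*% Er)
  b <- as.numeric(d %*% Ec)
  sum(e) / L - sum(a * b) / L^2
}

# Given row labels, the Q-optimal label for every column (and symmetrically
# for rows given column labels): affinity(f, m) = sum_{s in m} A_sf -
# d_f * (sum_{s in m} k_s) / L. A node whose best affinity is negative is
# better off alone (contribution 0) and gets a fresh singleton label.
assign_side <- function(A, own_deg, other_deg, other_labels, L, next_label) {
  labs <- sort(unique(other_labels))
  ind <- outer(other_labels, labs, "==") * 1          # |other| x M
  overlap <- t(A) %*% ind                             # n x M links into module
  mod_deg <- as.numeric(other_deg %*% ind)            # a_m (or b_m)
  affinity <- overlap - outer(own_deg, mod_deg) / L
  best <- max.col(affinity, ties.method = "first")
  best_val <- affinity[cbind(seq_along(best), best)]
  out <- labs[best]
  lone <- best_val < 0
  if (any(lone)) {
    out[lone] <- seq.int(next_label, length.out = sum(lone))
  }
  out
}

#' Barber bipartite modularity
#'
#' Maximizes Barber's bipartite modularity
#' Q = (1/L) sum (A_sf - k_s d_f / L) over node pairs sharing a module,
#' by seeded label propagation with greedy module agglomeration
#' (LPAwb+-style): each restart initializes every tree in its own module,
#' alternates Q-optimal reassignment of OTU and tree labels until Q stops
#' improving, then greedily merges module pairs while any merge increases Q.
#' The best of `restarts` restarts is returned; deterministic given `seed`.
#'
#' @param web Binary web matrix (trees x OTUs) with at least one link.
#' @param seed Integer seed for the restart randomization.
#' @param restarts Number of random restarts (default 20).
#' @return A list: `q` (modularity of the best partition), `n_modules`
#'   (modules in that partition), `row_labels`, `col_labels` (integer module
#'   ids per tree / OTU).
#' @export
modularity <- function(web, seed = 1L, restarts = 20L) {
  check_web(web)
  L <- sum(web)
  if (L == 0) stop("web has no links", call. = FALSE)
  I <- nrow(web)
  J <- ncol(web)
  k <- rowSums(web)
  d <- colSums(web)

  propagate <- function(row_labels) {
    col_labels <- rep.int(0L, J)
    q_prev <- -Inf
    for (it in 1:100) {
      nl <- max(row_labels) + 1L
      col_labels <- assign_side(web, d, k, row_labels, L, nl)
      nl <- max(col_labels, row_labels) + 1L
      row_labels <- assign_side(t(web), k, d, col_labels, L, nl)
      q <- barber_q(web, row_labels, col_labels)
      if (q <= q_prev + 1e-12) break
      q_prev <- q
    }
    list(row_labels = row_labels, col_labels = col_labels)
  }

  agglomerate <- function(row_labels, col_labels) {
    # greedy agglomeration: merge the module pair with the largest positive gain
    repeat {
      labs <- sort(unique(c(row_labels, col_labels)))
      if (length(labs) < 2) break
      Er <- outer(row_labels, labs, "==") * 1        # I x M
      Ec <- outer(col_labels, labs, "==") * 1        # J x M
      E <- t(Er) %*% web %*% Ec                      # links m1-rows x m2-cols
      a <- as.numeric(k %*% Er)
      b <- as.numeric(d %*% Ec)
      gain <- (E + t(E)) / L - (outer(a, b) + outer(b, a)) / L^2
      gain[lower.tri(gain, diag = TRUE)] <- 0
      gmax <- max(gain)
      if (gmax <= 1e-12) break
      ij <- which(gain == gmax, arr.ind = TRUE)[1, ]
      row_labels[row_labels == labs[ij[2]]] <- labs[ij[1]]
      col_labels[col_labels == labs[ij[2]]] <- labs[ij[1]]
    }
    list(row_labels = row_labels, col_labels = col_labels)
  }

  # one restart: alternate label propagation and agglomeration until the
  # partition stops improving
  one_restart <- function(row_init) {
    state <- propagate(row_init)
    q <- barber_q(web, state$row_labels, state$col_labels)
    repeat {
      state <- agglomerate(state$row_labels, state$col_labels)
      state <- propagate(state$row_labels)
      q_new <- barber_q(web, state$row_labels, state$col_labels)
      if (q_new <= q + 1e-12) break
      q <- q_new
    }
    list(q = q, row_labels = state$row_labels, col_labels = state$col_labels)
  }

  best <- NULL
  # restart 1 starts from all-singleton rows; later restarts from random
  # partitions with varying module counts to diversify the search
  inits <- with_local_seed(seed, c(
    list(seq_len(I)),
    replicate(max(0L, restarts - 1L), sample.int(I, I, replace = TRUE),
              simplify = FALSE)
  ))
  for (init in inits) {
    res <- one_restart(init)
    if (is.null(best) || res$q > best$q + 1e-12) best <- res
  }
  relabel <- match(c(best$row_labels, best$col_labels),
                   unique(c(best$row_labels, best$col_labels)))
  list(q = best$q,
       n_modules = max(relabel),
       row_labels = relabel[seq_len(I)],
       col_labels = relabel[I + seq_len(J)])
}
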