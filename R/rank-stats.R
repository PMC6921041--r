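# Average ranks (midranks) of a numeric vector.
midrank <- function(x) rank(x, ties.method = "average")

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on k - 1 degrees of freedom. Used across the pipeline to compare network
#' characteristics and phi coefficients between tree diversity levels and
#' fungal guilds.
#'
#' @param groups A list of numeric vectors (>= 2 groups, all nonempty), or a
#'   data frame with columns `value` and `group`.
#' @param value,group Column names when `groups` is a data frame.
#' @return An object of class `tw_kruskal` with elements `statistic`, `df`,
#'   `p.value`, `n`; supports [generics::tidy()] and [generics::glance()].
#' @export
kruskal_wallis <- function(groups, value = "value", group = "group") {
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]])
  }
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  if (N < 3) stop("need total n >= 3", call. = FALSE)
  r <- midrank(x)
  mean_ranks <- tapply(r, g, mean)
  n_i <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(n_i * (mean_ranks - (N + 1) / 2)^2)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (C > 0) H / C else 0        # all observations tied -> H = 0
  df <- length(groups) - 1L
  p <- pchisq(H, df, lower.tail = FALSE)
  structure(list(statistic = H, df = df, p.value = p, n = N,
                 mean_ranks = as.numeric(mean_ranks), n_i = as.integer(n_i)),
            class = "tw_kruskal")
}

#' Pairwise post hoc comparisons after Kruskal-Wallis
#'
#' Siegel-Castellan multiple comparisons of mean ranks: a pair (i, j) is
#' significant when |mean rank i - mean rank j| exceeds the critical
#' difference z * sqrt(N(N+1)/12 * (1/n_i + 1/n_j)), with the z quantile at
#' a Bonferroni-corrected level alpha / m (m pairs) or, with
#' `correction = "holm"`, step-down Holm levels alpha / (m - step + 1).
#'
#' @inheritParams kruskal_wallis
#' @param alpha Family-wise significance level.
#' @param correction `"bonferroni"` or `"holm"`.
#' @return A tibble with one row per pair: `group1`, `group2`, `diff`
#'   (absolute mean-rank difference), `critical_diff`, `significant`.
#' @export
kruskal_posthoc <- function(groups, alpha = 0.05,
                            correction = c("bonferroni", "holm"),
                            value = "value", group = "group") {
  correction <- match.arg(correction)
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]])
  }
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- midrank(x)
  mean_ranks <- tapply(r, g, mean)
  n_i <- lengths(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  m <- ncol(pairs)
  diff <- abs(mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]])
  se <- sqrt(N * (N + 1) / 12 * (1 / n_i[pairs[1, ]] + 1 / n_i[pairs[2, ]]))
  if (correction == "bonferroni") {
    cd <- qnorm(1 - alpha / (2 * m)) * se
    sig <- diff > cd
  } else {
    # Holm step-down on the standardized differences, largest first
    ord <- order(diff / se, decreasing = TRUE)
    cd <- numeric(m)
    sig <- logical(m)
    alive <- TRUE
    for (step in seq_len(m)) {
      i <- ord[step]
      cd[i] <- qnorm(1 - alpha / (2 * (m - step + 1))) * se[i]
      sig[i] <- alive && diff[i] > cd[i]
      if (!sig[i]) alive <- FALSE
    }
  }
  tibble::tibble(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                 diff = as.numeric(diff), critical_diff = as.numeric(cd),
                 significant = as.vector(sig))
}

#' Holm step-down p-value adjustment
#'
#' Sorted p-values are multiplied by (m - rank + 1), made monotone
#' non-decreasing, capped at 1, and returned in the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj <- pmin(1, p[ord] * (m - seq_len(m) + 1))
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Wilcoxon rank-sum test (Mann-Whitney)
#'
#' Two-sided two-sample rank-sum test. With `n_x + n_y <= 12` and no ties
#' the p-value is exact, from complete enumeration of the rank assignments;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples (nonempty).
#' @return An object of class `tw_ranksum` with `statistic` (the
#'   Mann-Whitney U of `x`), `p.value`, and `method` (`"exact"` or
#'   `"normal"`); supports [generics::tidy()].
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample", call. = FALSE)
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  z <- c(x, y)
  r <- midrank(z)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(z) > 0
  if (N <= 12 && !has_ties) {
    sets <- utils::combn(N, nx)
    ranks <- matrix(seq_len(N)[sets], nrow = nx)
    u_all <- colSums(ranks) - nx * (nx + 1) / 2
    dev <- abs(u_all - nx * ny / 2)
    p <- mean(dev >= abs(U - nx * ny / 2) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(z)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zstat <- (abs(U - nx * ny / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(max(zstat, 0), lower.tail = FALSE))
    }
    method <- "normal"
  }
  structure(list(statistic = U, p.value = p, method = method,
                 n_x = nx, n_y = ny),
            class = "tw_ranksum")
}

#' Format a p-value with a reporting floor
#'
#' Values below 1e-15 are reported as `"<1e-15"`; everything else at 3
#' significant digits.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-15, "<1e-15", formatC(p, digits = 3, format = "g"))
}

#' @export
print.tw_kruskal <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis rank-sum test: H = %.4g, df = %d, p = %s (n = %d)\n",
              x$statistic, x$df, format_pvalue(x$p.value), x$n))
  invisible(x)
}

#' @export
print.tw_ranksum <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum test (%s): U = %.4g, p = %s (n = %d, %d)\n",
              x$method, x$statistic, format_pvalue(x$p.value), x$n_x, x$n_y))
  invisible(x)
}
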