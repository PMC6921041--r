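#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Kruskal-Wallis result
#'
#' @param x A `tw_kruskal` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p.value`, `n`.
#' @export
tidy.tw_kruskal <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df,
                 p.value = x$p.value, n = x$n,
                 method = "Kruskal-Wallis rank-sum test")
}

#' @rdname tidy.tw_kruskal
#' @export
glance.tw_kruskal <- function(x, ...) tidy(x)

#' Tidy a Wilcoxon rank-sum result
#'
#' @param x A `tw_ranksum` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, sample sizes, method.
#' @export
tidy.tw_ranksum <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 n_x = x$n_x, n_y = x$n_y,
                 method = paste0("Wilcoxon rank-sum (", x$method, ")"))
}

#' @rdname tidy.tw_ranksum
#' @export
glance.tw_ranksum <- function(x, ...) tidy(x)
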