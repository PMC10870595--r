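#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a weighted mining result
#'
#' @param x A [mine_weighted()] result.
#' @param ... Unused.
#' @return The frequent-itemsets tibble (`itemset`, `k`, `count`,
#'   `hm_weight`, `weighted_support`, `level_min_support`).
#' @export
tidy.weighted_apriori <- function(x, ...) {
  dplyr::select(x$all_frequent, !"items")
}

#' @rdname tidy.weighted_apriori
#' @return For `glance()`: a one-row run summary.
#' @export
glance.weighted_apriori <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    n_items = length(x$item_weights),
    n_levels = length(x$levels),
    n_frequent = nrow(x$all_frequent),
    max_k = if (nrow(x$all_frequent)) max(x$all_frequent$k) else 0L,
    min_support_mode = x$config$min_support_mode,
    support_norm = x$config$support_norm
  )
}

#' Tidy a classic Apriori result
#'
#' @param x A [classic_apriori()] result.
#' @param ... Unused.
#' @return The frequent-itemsets tibble (`itemset`, `k`, `count`,
#'   `support`).
#' @export
tidy.classic_apriori <- function(x, ...) {
  dplyr::select(x$frequent, !"items")
}

#' @rdname tidy.classic_apriori
#' @export
glance.classic_apriori <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    min_support = x$min_support,
    n_frequent = nrow(x$frequent),
    max_k = if (nrow(x$frequent)) max(x$frequent$k) else 0L
  )
}

#' Tidy a method comparison
#'
#' @param x A [compare_methods()] result.
#' @param ... Unused.
#' @return The per-method summary tibble.
#' @export
tidy.mining_comparison <- function(x, ...) x$methods

#' @rdname tidy.mining_comparison
#' @export
glance.mining_comparison <- function(x, ...) {
  tibble::tibble(
    effective_threshold = x$effective_threshold,
    n_grid = nrow(x$grid),
    n_patterns_weighted = x$methods$n_patterns[x$methods$method == "weighted"],
    n_patterns_classic = x$methods$n_patterns[x$methods$method == "classic"],
    min_confidence = x$min_confidence
  )
}
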