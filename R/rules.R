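#' Weighted confidence of a rule
#'
#' The ratio of weighted supports,
#' `ws(antecedent + consequent) / ws(antecedent)`. With equal weights
#' everywhere this reduces to classic confidence `count(A u B) / count(A)`
#' and lies in [0, 1]; with unequal weights the ratio can exceed 1 (the
#' harmonic mean of the union can beat the antecedent's), which is a real
#' property of the measure and is reported unclamped.
#'
#' @param rule_union Character vector: the full itemset A u B.
#' @param antecedent Character vector: a proper non-empty subset of
#'   `rule_union`.
#' @inheritParams weighted_support
#' @return A single non-negative number.
#' @export
weighted_confidence <- function(rule_union, antecedent, db, weights,
                                support_norm = c("records", "total_weight")) {
  support_norm <- match.arg(support_norm)
  if (length(antecedent) == 0L) abort_wapriori("antecedent must be non-empty.")
  if (!all(antecedent %in% rule_union)) {
    abort_wapriori("antecedent must be a subset of the rule union.")
  }
  if (length(setdiff(rule_union, antecedent)) == 0L) {
    abort_wapriori("consequent is empty: antecedent must be a proper subset of the union.")
  }
  ws_u <- weighted_support(rule_union, db, weights, support_norm)
  ws_a <- weighted_support(antecedent, db, weights, support_norm)
  if (ws_a == 0) abort_wapriori("antecedent has zero support; the rule is undefined.")
  ws_u / ws_a
}

#' Generate association rules from a mining result
#'
#' For every frequent itemset of size >= 2, every non-empty proper subset is
#' tried as antecedent (the complement is the consequent); rules meeting the
#' confidence threshold are kept, sorted by confidence descending with ties
#' broken by the antecedent's lexicographic order. For a weighted result the
#' confidence is the ratio of weighted supports; for the classic baseline it
#' is the ratio of raw counts.
#'
#' @param x A [mine_weighted()] or [classic_apriori()] result.
#' @param min_confidence Keep rules with confidence `>=` this value
#'   (default 0.7; must be non-negative).
#' @param ... Passed to methods.
#' @return A tibble, one row per rule: `antecedent`, `consequent`,
#'   `union_size`, `count`, then `weighted_support`/`weighted_confidence`
#'   (weighted result) or `support`/`confidence` (classic result).
#' @export
generate_rules <- function(x, min_confidence = 0.7, ...) {
  UseMethod("generate_rules")
}

# all non-empty proper subsets of a canonical itemset, as a list
proper_subsets <- function(items) {
  k <- length(items)
  out <- list()
  for (size in seq_len(k - 1L)) {
    combos <- utils::combn(items, size, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

rule_sort <- function(rules, conf_col) {
  if (nrow(rules) == 0L) return(rules)
  rules[order(-rules[[conf_col]], rules$antecedent, rules$consequent,
              method = "radix"), , drop = FALSE]
}

#' @rdname generate_rules
#' @export
generate_rules.weighted_apriori <- function(x, min_confidence = 0.7, ...) {
  if (min_confidence < 0) abort_wapriori("`min_confidence` must be non-negative.")
  freq <- x$all_frequent[x$all_frequent$k >= 2L, , drop = FALSE]
  empty <- tibble::tibble(antecedent = character(), consequent = character(),
                          union_size = integer(), count = integer(),
                          weighted_support = numeric(),
                          weighted_confidence = numeric())
  if (nrow(freq) == 0L) return(empty)
  iw <- x$item_weights
  denom <- if (x$config$support_norm == "records") x$n_records else sum(iw)
  ws_cache <- new.env(parent = emptyenv())
  ws_of <- function(items) {
    key <- itemset_key(items)
    if (!is.null(ws_cache[[key]])) return(ws_cache[[key]])
    v <- count_itemsets(x$db, list(items)) * harmonic_mean(iw[items]) / denom
    ws_cache[[key]] <- v
    v
  }
  rows <- list()
  for (i in seq_len(nrow(freq))) {
    u_items <- freq$items[[i]]
    ws_u <- freq$weighted_support[i]
    for (a in proper_subsets(u_items)) {
      ws_a <- ws_of(a)
      if (ws_a == 0) next   # undefined rule; antecedent never occurs
      conf <- ws_u / ws_a
      if (conf >= min_confidence) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          antecedent = itemset_key(a),
          consequent = itemset_key(setdiff(u_items, a)),
          union_size = length(u_items),
          count = freq$count[i],
          weighted_support = ws_u,
          weighted_confidence = conf)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- dplyr::bind_rows(rows)
  if (any(out$weighted_confidence > 1)) {
    rlang::inform(paste0(sum(out$weighted_confidence > 1),
                         " rule(s) have weighted confidence > 1 (the harmonic-mean ",
                         "measure is not bounded by 1 under unequal weights)."))
  }
  rule_sort(out, "weighted_confidence")
}

#' @rdname generate_rules
#' @export
generate_rules.classic_apriori <- function(x, min_confidence = 0.7, ...) {
  if (min_confidence < 0) abort_wapriori("`min_confidence` must be non-negative.")
  freq <- x$frequent[x$frequent$k >= 2L, , drop = FALSE]
  empty <- tibble::tibble(antecedent = character(), consequent = character(),
                          union_size = integer(), count = integer(),
                          support = numeric(), confidence = numeric())
  if (nrow(freq) == 0L) return(empty)
  # downward closure: every antecedent is itself frequent, so its count is
  # already in the table
  count_of <- stats::setNames(x$frequent$count, x$frequent$itemset)
  rows <- list()
  for (i in seq_len(nrow(freq))) {
    u_items <- freq$items[[i]]
    cnt_u <- freq$count[i]
    for (a in proper_subsets(u_items)) {
      cnt_a <- count_of[[itemset_key(a)]]
      conf <- cnt_u / cnt_a
      if (conf >= min_confidence) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          antecedent = itemset_key(a),
          consequent = itemset_key(setdiff(u_items, a)),
          union_size = length(u_items),
          count = cnt_u,
          support = freq$support[i],
          confidence = conf)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  rule_sort(dplyr::bind_rows(rows), "confidence")
}

#' Median rule confidence per itemset size
#'
#' Groups rules by the size of their union itemset (antecedent + consequent)
#' and returns the median confidence per group — the rule-quality summary
#' used to compare the weighted miner with the classic baseline. Sizes with
#' no rules are simply absent. Works on both the weighted and classic rule
#' tables.
#'
#' @param rules A tibble from [generate_rules()].
#' @return A tibble: `union_size`, `n_rules`, `median_confidence`.
#' @export
median_confidence_by_size <- function(rules) {
  stopifnot(is.data.frame(rules))
  conf_col <- if ("weighted_confidence" %in% names(rules)) "weighted_confidence" else "confidence"
  if (nrow(rules) == 0L) {
    return(tibble::tibble(union_size = integer(), n_rules = integer(),
                          median_confidence = numeric()))
  }
  rules |>
    dplyr::group_by(.data$union_size) |>
    dplyr::summarise(n_rules = dplyr::n(),
                     median_confidence = stats::median(.data[[conf_col]]),
                     .groups = "drop") |>
    dplyr::arrange(.data$union_size)
}
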