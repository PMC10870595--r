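# resolve a feature_weights table (or named numeric vector) into per-item
# weights for a given database
resolve_item_weights <- function(db, weights) {
  if (is.numeric(weights) && !is.null(names(weights))) return(weights)
  item_weights(db, weights)
}

#' Weighted support of an itemset
#'
#' The fraction of records containing every item of the set, scaled by the
#' harmonic mean of the member items' weights:
#' `count(itemset) * HM(weights) / N`. With all weights equal to 1 this
#' reduces to classic support. The alternative normalisation
#' `support_norm = "total_weight"` divides by the summed weight of all
#' retained items instead of the record count.
#'
#' @param itemset Character vector of item names (non-empty).
#' @param db A [transaction_db()].
#' @param weights A [feature_weights()] tibble or a named per-item weight
#'   vector.
#' @param support_norm `"records"` (default) or `"total_weight"`.
#' @return A single non-negative number.
#' @export
weighted_support <- function(itemset, db, weights,
                             support_norm = c("records", "total_weight")) {
  support_norm <- match.arg(support_norm)
  if (length(itemset) == 0L) abort_wapriori("itemset must be non-empty.")
  if (anyDuplicated(itemset)) abort_wapriori("itemset has duplicate items.")
  iw <- resolve_item_weights(db, weights)
  missing_w <- setdiff(itemset, names(iw))
  if (length(missing_w)) {
    abort_wapriori(paste0("no weight for item(s): ", paste(missing_w, collapse = ", ")))
  }
  count <- count_itemsets(db, list(itemset))
  denom <- if (support_norm == "records") db$n_records else sum(iw)
  count * harmonic_mean(iw[itemset]) / denom
}

#' Automatically generated minimum support for one level
#'
#' The level-wise threshold the weighted miner tests candidates against.
#' Two modes:
#' \describe{
#'   \item{`mean_of_supports` (default)}{the arithmetic mean of the
#'     candidates' weighted supports — a threshold on the same scale as the
#'     supports, so at every level roughly the above-average candidates
#'     survive.}
#'   \item{`literal_eq6`}{the summed weighted supports divided by the number
#'     of records, the literal displayed form of the level formula.}
#' }
#'
#' @param supports Numeric vector of candidate weighted supports, or a
#'   candidates tibble with a `weighted_support` column.
#' @param n_records Record count (required for `literal_eq6`).
#' @param mode `"mean_of_supports"` or `"literal_eq6"`.
#' @return A single number, strictly positive whenever any candidate has
#'   positive support.
#' @export
level_min_support <- function(supports, n_records = NULL,
                              mode = c("mean_of_supports", "literal_eq6")) {
  mode <- match.arg(mode)
  if (is.data.frame(supports)) supports <- supports$weighted_support
  if (length(supports) == 0L) abort_wapriori("no candidates: the mining loop must stop before computing a level threshold.")
  if (mode == "mean_of_supports") {
    mean(supports)
  } else {
    if (is.null(n_records)) abort_wapriori("`n_records` is required for mode 'literal_eq6'.")
    sum(supports) / n_records
  }
}

# build the candidates tibble for a list of same-size itemsets
candidate_table <- function(db, itemsets, iw, support_norm) {
  itemsets <- lapply(itemsets, lex_sort)
  keys <- vapply(itemsets, itemset_key, character(1))
  ord <- lex_order(keys)
  itemsets <- itemsets[ord]
  keys <- keys[ord]
  counts <- count_itemsets(db, itemsets)
  hm <- vapply(itemsets, function(s) harmonic_mean(iw[s]), numeric(1))
  denom <- if (support_norm == "records") db$n_records else sum(iw)
  tibble::tibble(
    itemset = keys,
    items = itemsets,
    k = lengths(itemsets),
    count = counts,
    hm_weight = hm,
    weighted_support = counts * hm / denom
  )
}

#' Candidate 1-itemsets with weighted supports
#'
#' One candidate per retained (weighted) item, counted in a single pass over
#' the database; the harmonic-mean weight of a singleton is its item weight.
#'
#' @inheritParams weighted_support
#' @return A tibble with columns `itemset`, `items` (list), `k`, `count`,
#'   `hm_weight`, `weighted_support`.
#' @export
create_c1 <- function(db, weights, support_norm = c("records", "total_weight")) {
  support_norm <- match.arg(support_norm)
  iw <- resolve_item_weights(db, weights)
  candidate_table(db, as.list(lex_sort(names(iw))), iw, support_norm)
}

#' Score one level of candidates and apply the automatic threshold
#'
#' Counts every candidate itemset in one pass over the records, computes the
#' level's minimum support with [level_min_support()], and keeps the
#' candidates whose weighted support meets it (inclusive `>=`). Zero-support
#' candidates never survive: an itemset absent from every record is not
#' frequent even in the degenerate level where all supports are zero.
#' Survivors are sorted by weighted support (descending), ties broken by the
#' lexicographic item tuple.
#'
#' @inheritParams weighted_support
#' @param candidates List of same-size character itemsets.
#' @param min_support_mode Passed to [level_min_support()], or `"fixed"` to
#'   use `fixed_min_support` at this level.
#' @param fixed_min_support Fixed threshold when `min_support_mode = "fixed"`.
#' @return A list of class `level_result`: `k`, `min_support`, `candidates`
#'   (tibble) and `survivors` (tibble).
#' @export
scan_level <- function(db, candidates, weights,
                       min_support_mode = c("mean_of_supports", "literal_eq6", "fixed"),
                       support_norm = c("records", "total_weight"),
                       fixed_min_support = NULL) {
  min_support_mode <- match.arg(min_support_mode)
  support_norm <- match.arg(support_norm)
  if (length(candidates) == 0L) abort_wapriori("no candidates to scan.")
  ks <- unique(lengths(candidates))
  if (length(ks) != 1L) abort_wapriori("candidates must all have the same size.")
  iw <- resolve_item_weights(db, weights)
  cand <- candidate_table(db, candidates, iw, support_norm)
  ms <- if (min_support_mode == "fixed") {
    if (is.null(fixed_min_support) || fixed_min_support <= 0) {
      abort_wapriori("`fixed_min_support` must be a positive number in fixed mode.")
    }
    fixed_min_support
  } else {
    level_min_support(cand$weighted_support, n_records = db$n_records,
                      mode = min_support_mode)
  }
  surv <- cand[cand$weighted_support >= ms & cand$weighted_support > 0, , drop = FALSE]
  surv <- surv[order(-surv$weighted_support, surv$itemset, method = "radix"), , drop = FALSE]
  structure(list(k = ks, min_support = ms, candidates = cand, survivors = surv),
            class = "level_result")
}

#' @export
print.level_result <- function(x, ...) {
  cat("<level_result> k = ", x$k, ": ", nrow(x$candidates), " candidates, ",
      nrow(x$survivors), " survivors at min support ",
      format(x$min_support, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Apriori candidate generation (join + prune)
#'
#' Builds the size-(k+1) candidates from frequent k-itemsets: the join step
#' merges pairs sharing their first k-1 items; the prune step discards any
#' candidate with a k-subset that is not frequent. Output is unique and in
#' canonical (lexicographic) order.
#'
#' @param itemsets List of character itemsets, all of size k.
#' @return List of character itemsets of size k+1 (possibly empty).
#' @examples
#' apriori_gen(list(c("A", "B"), c("A", "C"), c("B", "C")))
#' @export
apriori_gen <- function(itemsets) {
  if (length(itemsets) < 2L) return(list())
  canon <- lapply(itemsets, lex_sort)
  k <- unique(lengths(canon))
  if (length(k) != 1L) abort_wapriori("itemsets must all have the same size.")
  keys <- vapply(canon, itemset_key, character(1))
  if (anyDuplicated(keys)) abort_wapriori("itemsets must be unique.")
  prefix <- vapply(canon, function(s) paste(s[-k], collapse = "\r"), character(1))
  last <- vapply(canon, function(s) s[k], character(1))
  out <- list()
  for (grp in split(seq_along(canon), prefix)) {
    if (length(grp) < 2L) next
    ls <- lex_sort(last[grp])
    pre <- canon[[grp[1]]][-k]
    for (i in seq_len(length(ls) - 1L)) {
      for (j in seq.int(i + 1L, length(ls))) {
        out[[length(out) + 1L]] <- c(pre, ls[i], ls[j])
      }
    }
  }
  if (length(out) == 0L) return(list())
  out <- lapply(out, lex_sort)
  # prune: every k-subset must be frequent
  keep <- vapply(out, function(cand) {
    all(vapply(seq_along(cand), function(d) itemset_key(cand[-d]) %in% keys, logical(1)))
  }, logical(1))
  out <- out[keep]
  out_keys <- vapply(out, itemset_key, character(1))
  dup <- duplicated(out_keys)
  out <- out[!dup]
  out[lex_order(out_keys[!dup])]
}

#' Mine frequent itemsets with weighted support and automatic per-level
#' minimum support
#'
#' Level-wise Apriori search in which (i) every itemset's support is scaled
#' by the harmonic mean of its member items' information-gain weights and
#' (ii) the minimum-support threshold is generated automatically at each
#' level from the candidates' own supports, instead of being fixed by the
#' user. The loop runs candidate generation ([apriori_gen()]) and level
#' scanning ([scan_level()]) until a level has no survivors or no candidates
#' can be generated.
#'
#' Note that the weighted measure is not anti-monotone (a high-weight item
#' can raise the harmonic mean faster than the count drops), so the result
#' is faithful to the level-wise algorithm — candidates are built only from
#' the previous level's survivors — rather than an exhaustive enumeration of
#' all itemsets exceeding their level threshold.
#'
#' @inheritParams scan_level
#' @param weights A [feature_weights()] tibble (removed features' items are
#'   excluded) or a named per-item weight vector.
#' @param max_k Optional cap on the itemset size explored.
#' @return An object of class `weighted_apriori` with elements `levels`
#'   (list of [scan_level()] results), `all_frequent` (tibble of all
#'   surviving itemsets with their level thresholds), `config`, `db`,
#'   `item_weights` and `n_records`. Use [generics::tidy()] /
#'   [generics::glance()] or [generate_rules()] on it.
#' @export
mine_weighted <- function(db, weights,
                          min_support_mode = c("mean_of_supports", "literal_eq6", "fixed"),
                          support_norm = c("records", "total_weight"),
                          fixed_min_support = NULL, max_k = Inf) {
  min_support_mode <- match.arg(min_support_mode)
  support_norm <- match.arg(support_norm)
  stopifnot(inherits(db, "transaction_db"))
  iw <- resolve_item_weights(db, weights)
  levels <- list()
  cands <- as.list(lex_sort(names(iw)))
  k <- 1L
  while (length(cands) > 0L && k <= max_k) {
    lvl <- scan_level(db, cands, iw,
                      min_support_mode = min_support_mode,
                      support_norm = support_norm,
                      fixed_min_support = fixed_min_support)
    levels[[k]] <- lvl
    if (nrow(lvl$survivors) == 0L) break
    cands <- apriori_gen(lvl$survivors$items)
    k <- k + 1L
  }
  all_frequent <- dplyr::bind_rows(lapply(levels, function(l) {
    if (nrow(l$survivors) == 0L) return(NULL)
    dplyr::mutate(l$survivors, level_min_support = l$min_support)
  }))
  if (is.null(all_frequent) || nrow(all_frequent) == 0L) {
    all_frequent <- tibble::tibble(
      itemset = character(), items = list(), k = integer(), count = integer(),
      hm_weight = numeric(), weighted_support = numeric(),
      level_min_support = numeric())
  }
  structure(
    list(levels = levels, all_frequent = all_frequent,
         config = list(min_support_mode = min_support_mode,
                       support_norm = support_norm,
                       fixed_min_support = fixed_min_support,
                       entropy_base = 2,
                       n_records = db$n_records,
                       n_items = length(iw)),
         db = db, item_weights = iw, n_records = db$n_records),
    class = "weighted_apriori"
  )
}

#' @export
print.weighted_apriori <- function(x, ...) {
  cat("<weighted_apriori> ", nrow(x$all_frequent), " frequent itemsets over ",
      length(x$levels), " level(s); ", x$n_records, " records, ",
      length(x$item_weights), " weighted items\n", sep = "")
  cat("min support mode: ", x$config$min_support_mode,
      "; support norm: ", x$config$support_norm, "\n", sep = "")
  for (l in x$levels) {
    cat("  k=", l$k, ": ", nrow(l$candidates), " candidates -> ",
        nrow(l$survivors), " survivors (min support ",
        format(l$min_support, digits = 4), ")\n", sep = "")
  }
  invisible(x)
}
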