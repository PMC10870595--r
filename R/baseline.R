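#' Classic Apriori with a fixed user-set minimum support
#'
#' The unweighted baseline: level-wise mining where an itemset is frequent
#' when its plain support (count / N) meets the fixed threshold (inclusive
#' `>=`, matching the weighted miner so equal-weight equivalence is exact).
#' Downward closure holds for plain support, so the level-wise result equals
#' the exhaustive one.
#'
#' The implementation is intentionally independent of [mine_weighted()]'s
#' internals: itemset presence vectors are built by incremental conjunction
#' and candidates by extending each frequent k-set with frequent single
#' items beyond its last member (then subset-pruned), so the two routes can
#' cross-check each other.
#'
#' @param db A [transaction_db()].
#' @param min_support Fixed threshold in (0, 1].
#' @param max_k Optional cap on itemset size.
#' @return An object of class `classic_apriori` with elements `frequent`
#'   (tibble: `itemset`, `items`, `k`, `count`, `support`), `min_support`,
#'   `db` and `n_records`.
#' @export
classic_apriori <- function(db, min_support, max_k = Inf) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    abort_wapriori("`min_support` must lie in (0, 1].")
  }
  mat <- db$matrix
  n <- db$n_records
  items <- lex_sort(db$items)
  counts1 <- vapply(items, function(it) sum(mat[, it]), numeric(1))
  f1 <- items[counts1 / n >= min_support]
  rows <- list()
  # presence vector per frequent itemset, keyed by canonical itemset string
  pres <- list()
  for (it in f1) {
    pres[[it]] <- mat[, it]
    rows[[it]] <- list(items = it, count = sum(mat[, it]))
  }
  level <- lapply(f1, identity)
  k <- 1L
  while (length(level) > 0L && k < max_k) {
    level_keys <- vapply(level, itemset_key, character(1))
    nxt <- list()
    for (s in level) {
      beyond <- f1[f1 > s[length(s)]]
      for (it in beyond) {
        cand <- c(s, it)   # already canonical: s sorted, it > max(s)
        subs_ok <- all(vapply(seq_along(cand), function(d) {
          itemset_key(cand[-d]) %in% level_keys
        }, logical(1)))
        if (!subs_ok) next
        v <- pres[[itemset_key(s)]] & mat[, it]
        cnt <- sum(v)
        if (cnt / n >= min_support) {
          key <- itemset_key(cand)
          pres[[key]] <- v
          rows[[key]] <- list(items = cand, count = cnt)
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    level <- nxt
    k <- k + 1L
  }
  if (length(rows) == 0L) {
    frequent <- tibble::tibble(itemset = character(), items = list(),
                               k = integer(), count = integer(),
                               support = numeric())
  } else {
    keys <- names(rows)
    ord <- lex_order(vapply(rows, function(r) length(r$items), integer(1)),
                     keys)
    frequent <- tibble::tibble(
      itemset = unname(keys[ord]),
      items = unname(lapply(rows[ord], `[[`, "items")),
      k = unname(vapply(rows[ord], function(r) length(r$items), integer(1))),
      count = unname(vapply(rows[ord], function(r) as.integer(r$count), integer(1)))
    )
    frequent$support <- frequent$count / n
  }
  structure(list(frequent = frequent, min_support = min_support,
                 db = db, n_records = n),
            class = "classic_apriori")
}

#' @export
print.classic_apriori <- function(x, ...) {
  cat("<classic_apriori> ", nrow(x$frequent), " frequent itemsets at fixed min support ",
      format(x$min_support, digits = 4), " (", x$n_records, " records)\n", sep = "")
  invisible(x)
}

#' Sweep the classic miner across a grid of minimum-support thresholds
#'
#' Runs [classic_apriori()] (and rule generation) at each threshold of an
#' ascending grid and records pattern and rule counts — the comparison curve
#' the weighted miner's single automatic operating point is plotted against.
#' Counts are non-increasing in the threshold. Each threshold gets a wall
#' time budget; a run that exceeds it is recorded as not finished (`NA`
#' counts) rather than hanging.
#'
#' @param db A [transaction_db()].
#' @param grid Ascending numeric vector of thresholds in (0, 1].
#' @param min_confidence Confidence threshold for rule counting (default 0,
#'   i.e. all rules).
#' @param time_budget Seconds allowed per threshold (default 60).
#' @return A tibble: `min_support`, `n_patterns`, `n_rules`, `seconds`,
#'   `completed`.
#' @export
sweep_min_support <- function(db, grid, min_confidence = 0, time_budget = 60) {
  stopifnot(is.numeric(grid), length(grid) >= 1L)
  if (is.unsorted(grid)) abort_wapriori("`grid` must be sorted ascending.")
  res <- lapply(grid, function(th) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch({
      setTimeLimit(elapsed = time_budget, transient = TRUE)
      on.exit(setTimeLimit(elapsed = Inf, transient = TRUE), add = TRUE)
      fit <- classic_apriori(db, min_support = th)
      rules <- generate_rules(fit, min_confidence = min_confidence)
      list(n_patterns = nrow(fit$frequent), n_rules = nrow(rules), completed = TRUE)
    }, error = function(e) list(n_patterns = NA_integer_, n_rules = NA_integer_,
                                completed = FALSE))
    tibble::tibble(min_support = th,
                   n_patterns = out$n_patterns,
                   n_rules = out$n_rules,
                   seconds = proc.time()[["elapsed"]] - t0,
                   completed = out$completed)
  })
  dplyr::bind_rows(res)
}
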