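# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: counting is a per-record loop over item names,
# candidate generation is exhaustive subset enumeration, and information
# gain is computed through the mutual-information identity on the joint
# contingency table.

oracle_count <- function(mat, items) {
  hits <- 0L
  for (i in seq_len(nrow(mat))) {
    present <- colnames(mat)[mat[i, ] > 0]
    if (all(items %in% present)) hits <- hits + 1L
  }
  hits
}

oracle_hm <- function(v) 1 / mean(1 / v)

oracle_ws <- function(mat, items, w, norm = "records") {
  cnt <- oracle_count(mat, items)
  denom <- if (norm == "records") nrow(mat) else sum(w)
  cnt * oracle_hm(w[items]) / denom
}

# level-wise recount: given the universe of weighted items, replay the
# search with exhaustive candidate enumeration (a size-(k+1) set is a
# candidate iff every k-subset survived the previous level) and direct
# application of the weighted-support and level-threshold formulas
oracle_levels <- function(mat, w, mode = "mean_of_supports", norm = "records") {
  items <- sort(names(w), method = "radix")
  key <- function(s) paste(s, collapse = " & ")
  cands <- lapply(items, identity)
  out <- list()
  k <- 1L
  while (length(cands) > 0L) {
    ws <- vapply(cands, function(s) oracle_ws(mat, s, w, norm), numeric(1))
    ms <- if (mode == "mean_of_supports") mean(ws) else sum(ws) / nrow(mat)
    keep <- ws >= ms & ws > 0
    surv <- cands[keep]
    out[[k]] <- list(
      k = k,
      candidates = vapply(cands, key, character(1)),
      supports = ws,
      min_support = ms,
      survivors = vapply(surv, key, character(1)))
    if (length(surv) == 0L) break
    surv_keys <- out[[k]]$survivors
    pool <- sort(unique(unlist(surv)), method = "radix")
    cands <- list()
    if (length(pool) >= k + 1L) {
      for (cand in utils::combn(pool, k + 1L, simplify = FALSE)) {
        subs <- utils::combn(cand, k, simplify = FALSE)
        if (all(vapply(subs, key, character(1)) %in% surv_keys)) {
          cands[[length(cands) + 1L]] <- cand
        }
      }
    }
    k <- k + 1L
  }
  out
}

# exhaustive classic Apriori: every non-empty itemset with support >= t
# (valid because plain support is anti-monotone); returns canonical keys
oracle_classic <- function(mat, min_support, max_k = Inf) {
  items <- sort(colnames(mat), method = "radix")
  n <- nrow(mat)
  keys <- character(0)
  for (k in seq_len(min(length(items), max_k))) {
    any_this_size <- FALSE
    for (s in utils::combn(items, k, simplify = FALSE)) {
      cnt <- sum(rowSums(mat[, s, drop = FALSE] > 0) == k)
      if (cnt / n >= min_support) {
        keys <- c(keys, paste(s, collapse = " & "))
        any_this_size <- TRUE
      }
    }
    if (!any_this_size) break  # anti-monotonicity: no larger set can pass
  }
  sort(keys, method = "radix")
}

# classic rules by enumeration: all antecedent splits of frequent itemsets
oracle_classic_rules <- function(mat, min_support, min_confidence) {
  freq <- oracle_classic(mat, min_support)
  sets <- strsplit(freq, " & ", fixed = TRUE)
  out <- character(0)
  for (s in sets[lengths(sets) >= 2L]) {
    cnt_u <- oracle_count(mat, s)
    for (asz in seq_len(length(s) - 1L)) {
      for (a in utils::combn(s, asz, simplify = FALSE)) {
        conf <- cnt_u / oracle_count(mat, a)
        if (conf >= min_confidence) {
          out <- c(out, paste(paste(a, collapse = " & "), "=>",
                              paste(setdiff(s, a), collapse = " & ")))
        }
      }
    }
  }
  sort(out, method = "radix")
}

# mutual information I(X;Y) in bits from the joint table: an independent
# route to information gain
oracle_ig <- function(feature, class) {
  tab <- table(feature, class)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pxy <- tab[i, j] / n
      if (pxy == 0) next
      px <- sum(tab[i, ]) / n
      py <- sum(tab[, j]) / n
      mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

# seeded random transaction matrices with item-specific densities
random_mat <- function(n_records, n_items, seed) {
  set.seed(seed)
  probs <- runif(n_items, 0.15, 0.85)
  m <- vapply(probs, function(p) rbinom(n_records, 1L, p), integer(n_records))
  m <- matrix(m, nrow = n_records,
              dimnames = list(NULL, sprintf("i%02d", seq_len(n_items))))
  # ensure no empty record column-set pathologies matter; matrix as-is
  m
}

random_item_weights <- function(items, seed) {
  set.seed(seed)
  stats::setNames(runif(length(items), 0.05, 1), items)
}

split_itemset <- function(key) strsplit(key, " & ", fixed = TRUE)[[1]]

rule_keys <- function(rules) {
  if (nrow(rules) == 0L) return(character(0))
  sort(paste(rules$antecedent, "=>", rules$consequent), method = "radix")
}
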