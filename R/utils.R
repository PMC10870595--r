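# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# C-locale lexicographic sort: deterministic across platforms/locales
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(...) order(..., method = "radix")

# canonical string key for an itemset (items already sorted); the separator
# must never occur inside an item name (enforced by transaction_db) because
# category labels themselves may contain commas
ITEMSET_SEP <- " & "

itemset_key <- function(items) paste(items, collapse = ITEMSET_SEP)

# split a key back into items
split_key <- function(key) strsplit(key, ITEMSET_SEP, fixed = TRUE)[[1]]

# statistical mode with deterministic lexicographic tie-break
mode_stat <- function(x) {
  x <- x[!is.na(x)]
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  lex_sort(winners)[1]
}

is_binary_matrix <- function(m) {
  if (is.logical(m)) return(TRUE)
  all(m %in% c(0, 1))
}

abort_wapriori <- function(msg, class = "wapriori_error") {
  rlang::abort(msg, class = class)
}
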