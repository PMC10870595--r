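#' Construct a transaction database
#'
#' A `transaction_db` is the binary (records x items) presence/absence
#' container that all mining functions consume. Items are named
#' `"<feature>=<category>"`; each item remembers the feature it was derived
#' from so that feature-level weights can be inherited by items.
#'
#' Most users will build one with [encode_transactions()] rather than calling
#' this constructor directly; the constructor is useful for basket-style data
#' where every item is its own feature.
#'
#' @param matrix A logical or 0/1 numeric matrix, one row per record and one
#'   column per item. Column names are used as item identifiers; when absent,
#'   items are named `item1 ... itemM`.
#' @param item_feature Optional character vector, same length as the number
#'   of items, giving the source feature of each item. Defaults to the item
#'   names themselves (basket semantics: one feature per item).
#' @return An object of class `transaction_db`: a list with elements
#'   `matrix` (logical), `items` (character), `item_feature` (named
#'   character, item -> feature) and `n_records`.
#' @examples
#' m <- rbind(c(1, 0, 1), c(0, 1, 1))
#' colnames(m) <- c("a", "b", "c")
#' db <- transaction_db(m)
#' db$n_records
#' @export
transaction_db <- function(matrix, item_feature = NULL) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (!is_binary_matrix(matrix)) {
    abort_wapriori("`matrix` must be strictly binary (0/1 or logical).")
  }
  if (nrow(matrix) < 1L) abort_wapriori("a transaction_db needs at least one record.")
  if (ncol(matrix) < 1L) abort_wapriori("a transaction_db needs at least one item.")
  items <- colnames(matrix) %||% paste0("item", seq_len(ncol(matrix)))
  if (anyDuplicated(items)) abort_wapriori("item names must be unique.")
  if (any(grepl(ITEMSET_SEP, items, fixed = TRUE))) {
    abort_wapriori(paste0("item names must not contain the itemset separator '",
                          ITEMSET_SEP, "'."))
  }
  storage <- matrix(as.logical(matrix), nrow = nrow(matrix),
                    dimnames = list(NULL, items))
  item_feature <- item_feature %||% items
  if (length(item_feature) != length(items)) {
    abort_wapriori("`item_feature` must have one entry per item.")
  }
  names(item_feature) <- items
  structure(
    list(matrix = storage, items = items,
         item_feature = item_feature, n_records = nrow(storage)),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("<transaction_db> ", x$n_records, " records x ", length(x$items),
      " items (", length(unique(x$item_feature)), " features)\n", sep = "")
  shown <- utils::head(x$items, 8L)
  cat("items: ", paste(shown, collapse = ", "),
      if (length(x$items) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.transaction_db <- function(x) dim(x$matrix)

#' Tidy a transaction database into a dense 0/1 tibble
#'
#' @param x A [transaction_db()].
#' @param ... Unused.
#' @return A tibble with one 0/1 integer column per item.
#' @export
as_tibble.transaction_db <- function(x, ...) {
  m <- x$matrix
  storage.mode(m) <- "integer"
  tibble::as_tibble(as.data.frame(m, check.names = FALSE))
}

# items of each record as a list of character vectors
db_baskets <- function(db) {
  apply(db$matrix, 1L, function(r) db$items[r], simplify = FALSE)
}

# count records containing every item of each itemset (one pass per level)
count_itemsets <- function(db, itemsets) {
  if (length(itemsets) == 0L) return(integer(0))
  mat <- db$matrix
  vapply(itemsets, function(items) {
    idx <- match(items, db$items)
    if (anyNA(idx)) abort_wapriori(
      paste0("unknown item(s): ",
             paste(items[is.na(idx)], collapse = ", ")))
    k <- length(idx)
    if (k == 1L) sum(mat[, idx]) else sum(rowSums(mat[, idx, drop = FALSE]) == k)
  }, integer(1))
}
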