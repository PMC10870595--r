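# Shannon entropy in bits of a categorical vector
entropy_bits <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature with respect to a class
#'
#' The reduction in class entropy achieved by conditioning on the feature,
#' `H(class) - sum_v p(v) H(class | feature = v)`, with entropies in bits
#' (log base 2). The result lies in `[0, H(class)]`: 0 when the feature
#' carries no information about the class (e.g. a constant feature), and
#' `H(class)` when the feature determines the class exactly.
#'
#' @param feature A categorical vector (numeric vectors should be binned
#'   first; values are compared as-is).
#' @param class A categorical vector of the same length.
#' @return A single non-negative number (bits).
#' @examples
#' information_gain(c("a", "a", "b", "b"), c("x", "x", "y", "y")) # 1 bit
#' @export
information_gain <- function(feature, class) {
  if (length(feature) != length(class)) {
    abort_wapriori("`feature` and `class` must have the same length.")
  }
  if (length(class) < 1L) abort_wapriori("empty columns.")
  feature <- as.character(feature)
  class <- as.character(class)
  h <- entropy_bits(class)
  cond <- 0
  n <- length(class)
  for (v in unique(feature)) {
    sel <- feature == v
    cond <- cond + (sum(sel) / n) * entropy_bits(class[sel])
  }
  # guard tiny negative residue from floating-point cancellation
  max(h - cond, 0)
}

#' Information-gain weights for every feature of a table
#'
#' Computes the information gain of each feature column against the class
#' column, marks features whose gain falls below `threshold` (default
#' 0.001 bits) for removal, and returns the result as a tidy table. Items
#' derived from a feature inherit the feature's weight during mining.
#' Numeric columns are discretized with the same equal-width binning used by
#' [encode_transactions()] so that weights and items describe the same
#' categories.
#'
#' @param data A data frame containing the class column.
#' @param class_column Name of the categorical outcome column the gains are
#'   computed against.
#' @param threshold Removal threshold in bits (default 0.001): features with
#'   weight strictly below it are flagged `removed` and their items are
#'   excluded from all downstream mining.
#' @param numeric_bins Bins for numeric columns (default 3); keep equal to
#'   the value used when encoding.
#' @return A `feature_weights` tibble with columns `feature`, `weight`
#'   (bits) and `removed` (logical), and attributes `class_column`,
#'   `threshold` and `entropy_base` (= 2).
#' @export
feature_weights <- function(data, class_column, threshold = 0.001,
                            numeric_bins = 3) {
  stopifnot(is.data.frame(data))
  if (!class_column %in% names(data)) {
    abort_wapriori(paste0("class column '", class_column, "' not found."))
  }
  cls <- as.character(data[[class_column]])
  feats <- setdiff(names(data), class_column)
  if (length(feats) == 0L) abort_wapriori("no feature columns besides the class.")
  w <- vapply(feats, function(f) {
    x <- data[[f]]
    if (is.numeric(x)) x <- discretize_numeric(x, numeric_bins)
    information_gain(x, cls)
  }, numeric(1))
  out <- tibble::tibble(feature = feats, weight = unname(w)) |>
    remove_low_weight_features(threshold = threshold)
  attr(out, "class_column") <- class_column
  attr(out, "entropy_base") <- 2
  out
}

#' Flag features whose weight falls below a threshold
#'
#' Features with `weight < threshold` (strict) are marked `removed`; their
#' items never enter candidate generation. The comparison is strict, so a
#' threshold of 0 removes nothing (weights are non-negative).
#'
#' @param weights A tibble with columns `feature` and `weight` (e.g. from
#'   [feature_weights()]).
#' @param threshold Removal threshold (default 0.001).
#' @return The tibble with a (re)computed `removed` column; errors if every
#'   feature would be removed.
#' @export
remove_low_weight_features <- function(weights, threshold = 0.001) {
  stopifnot(is.data.frame(weights), all(c("feature", "weight") %in% names(weights)))
  if (any(weights$weight < 0)) abort_wapriori("weights must be non-negative.")
  out <- dplyr::mutate(tibble::as_tibble(weights), removed = .data$weight < threshold)
  if (all(out$removed)) {
    abort_wapriori("every feature falls below the weight threshold; nothing to mine.")
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("feature_weights", class(tibble::tibble()))
  out
}

#' Harmonic mean of positive values
#'
#' `n / sum(1/x)`. Always between the minimum and the maximum, and never
#' above the arithmetic mean; equal to it only when all values coincide.
#'
#' @param x A non-empty numeric vector of strictly positive values.
#' @return A single number.
#' @examples
#' harmonic_mean(c(0.2, 0.3)) # 0.24
#' @export
harmonic_mean <- function(x) {
  if (length(x) == 0L) abort_wapriori("harmonic_mean() of an empty vector is undefined.")
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort_wapriori("harmonic_mean() requires strictly positive finite values.")
  }
  length(x) / sum(1 / x)
}

#' Per-item weights inherited from feature weights
#'
#' Maps each retained item of a transaction database to the weight of its
#' source feature. Items whose feature was removed are dropped. When the
#' removal threshold is 0, surviving zero weights are clamped to
#' `zero_epsilon` (with a warning) so the harmonic mean stays defined.
#'
#' @param db A [transaction_db()].
#' @param weights A [feature_weights()] tibble (or any tibble with
#'   `feature`, `weight` and optionally `removed` columns).
#' @param zero_epsilon Replacement for exact-zero surviving weights
#'   (default 1e-9).
#' @return A named numeric vector, item -> weight, covering exactly the
#'   items of non-removed features.
#' @export
item_weights <- function(db, weights, zero_epsilon = 1e-9) {
  stopifnot(inherits(db, "transaction_db"), is.data.frame(weights))
  if (!"removed" %in% names(weights)) weights$removed <- FALSE
  kept <- weights[!weights$removed, , drop = FALSE]
  w <- stats::setNames(kept$weight, kept$feature)
  feat <- db$item_feature
  sel <- feat %in% names(w)
  iw <- w[feat[sel]]
  names(iw) <- db$items[sel]
  if (length(iw) == 0L) abort_wapriori("no weighted items remain in the database.")
  if (any(iw == 0)) {
    rlang::warn(paste0(sum(iw == 0), " surviving item weight(s) are exactly 0; ",
                       "clamped to ", zero_epsilon, " for the harmonic mean."))
    iw[iw == 0] <- zero_epsilon
  }
  iw
}
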