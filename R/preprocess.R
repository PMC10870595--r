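#' Remove outlying records from numeric columns
#'
#' Flags a record when any numeric column value lies more than `z_threshold`
#' robust standard deviations from the column centre, using the median and
#' the scaled median absolute deviation (MAD x 1.4826). The robust scale is
#' used because a plain mean/sd z-score masks exactly the gross outliers this
#' step exists to drop: a single extreme value inflates the sd enough to keep
#' itself below any sensible threshold.
#'
#' Categorical columns are untouched. Constant numeric columns contain no
#' outliers by convention. When the MAD is zero but the column is not
#' constant, any value different from the median is treated as an outlier
#' (the limit of the rule as the bulk of the column collapses onto one
#' value). Missing values are never flagged.
#'
#' @param data A data frame with one row per record.
#' @param z_threshold Positive number of robust standard deviations beyond
#'   which a value is an outlier (default 3).
#' @return A tibble with the flagged rows removed (never more rows than the
#'   input).
#' @examples
#' remove_outliers(data.frame(x = c(1, 1, 1, 1, 100)))
#' @export
remove_outliers <- function(data, z_threshold = 3) {
  stopifnot(is.data.frame(data), is.numeric(z_threshold), z_threshold > 0)
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(num_cols) == 0L) return(tibble::as_tibble(data))
  bad <- rep(FALSE, nrow(data))
  for (col in num_cols) {
    x <- data[[col]]
    ctr <- stats::median(x, na.rm = TRUE)
    scale <- stats::mad(x, center = ctr, na.rm = TRUE)
    dev <- abs(x - ctr)
    flag <- if (is.na(scale) || scale == 0) {
      # constant column -> no outliers; zero MAD otherwise -> any deviation
      if (all(dev == 0, na.rm = TRUE)) rep(FALSE, length(dev)) else dev > 0
    } else {
      dev / scale > z_threshold
    }
    flag[is.na(flag)] <- FALSE
    bad <- bad | flag
  }
  if (all(bad)) {
    abort_wapriori(
      "remove_outliers() would drop every record; lower `z_threshold` or inspect the data.")
  }
  tibble::as_tibble(data[!bad, , drop = FALSE])
}

#' Impute missing values (mean for numeric, mode for categorical)
#'
#' Numeric gaps are replaced by the column mean over non-missing values;
#' categorical gaps by the most frequent category, with ties broken by
#' lexicographic order of the category label so the result is deterministic.
#' In character columns the empty string and the tokens in `na_tokens` are
#' treated as missing before imputation.
#'
#' @param data A data frame.
#' @param na_tokens Character values treated as missing in categorical
#'   columns, in addition to `NA` (default `""` and `"NA"`).
#' @return A tibble with no missing values. Idempotent: applying it twice
#'   equals applying it once.
#' @examples
#' impute_missing(data.frame(x = c(2, NA, 4), g = c("a", "a", NA)))
#' @export
impute_missing <- function(data, na_tokens = c("", "NA")) {
  stopifnot(is.data.frame(data))
  out <- tibble::as_tibble(data)
  for (col in names(out)) {
    x <- out[[col]]
    if (is.factor(x)) x <- as.character(x)
    if (is.character(x)) x[x %in% na_tokens] <- NA_character_
    if (all(is.na(x))) {
      abort_wapriori(paste0("column '", col, "' is entirely missing; nothing to impute from."))
    }
    if (anyNA(x)) {
      if (is.numeric(x)) {
        x[is.na(x)] <- mean(x, na.rm = TRUE)
      } else {
        x[is.na(x)] <- mode_stat(x)
      }
    }
    out[[col]] <- x
  }
  out
}

#' Min-max normalize numeric columns to [0, 1]
#'
#' Maps each numeric column through (x - min) / (max - min). Constant
#' columns map to 0 by convention. Categorical columns are untouched.
#' Idempotent, because the extremes of a normalized column are 0 and 1.
#'
#' @param data A data frame (typically already imputed).
#' @return A tibble.
#' @examples
#' normalize_minmax(data.frame(x = c(10, 20, 30)))
#' @export
normalize_minmax <- function(data) {
  stopifnot(is.data.frame(data))
  out <- tibble::as_tibble(data)
  for (col in names(out)) {
    x <- out[[col]]
    if (!is.numeric(x)) next
    rng <- range(x, na.rm = TRUE)
    out[[col]] <- if (rng[1] == rng[2]) rep(0, length(x)) else (x - rng[1]) / (rng[2] - rng[1])
  }
  out
}

# equal-width bins over [0, 1]; values are rescaled first when they fall
# outside the unit interval (so the function is well defined on raw columns)
discretize_numeric <- function(x, bins) {
  stopifnot(is.numeric(x), bins >= 1)
  rng <- range(x, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    x <- if (rng[1] == rng[2]) rep(0, length(x)) else (x - rng[1]) / (rng[2] - rng[1])
  }
  idx <- pmin(floor(x * bins) + 1L, as.integer(bins))
  paste0("bin", idx)
}

#' One-hot encode a clean table into a transaction database
#'
#' Every observed (feature, category) pair becomes a binary item named
#' `"<feature>=<category>"`. Numeric columns are first cut into
#' `numeric_bins` equal-width intervals over [0, 1] (apply
#' [normalize_minmax()] beforehand; raw columns are rescaled on the fly) and
#' labelled `bin1 ... binK`. Item order is deterministic: features in column
#' order, categories in C-locale lexicographic order.
#'
#' For every record, exactly one item per encoded feature is set (the
#' one-hot property), so the number of set items per record equals the
#' number of encoded features.
#'
#' @param data A clean (imputed) data frame.
#' @param numeric_bins Number of equal-width bins for numeric columns
#'   (default 3).
#' @param exclude Optional character vector of column names to leave out of
#'   the encoding (e.g. an outcome column that should steer the feature
#'   weights but not be mined as items).
#' @return A [transaction_db()].
#' @examples
#' encode_transactions(data.frame(Sex = c("male", "female", "male")))
#' @export
encode_transactions <- function(data, numeric_bins = 3, exclude = NULL) {
  stopifnot(is.data.frame(data))
  keep <- setdiff(names(data), exclude)
  if (length(keep) == 0L) abort_wapriori("no columns left to encode.")
  if (nrow(data) < 1L) abort_wapriori("cannot encode an empty table.")
  cols <- list()
  feats <- character(0)
  for (col in keep) {
    x <- data[[col]]
    if (anyNA(x)) {
      abort_wapriori(paste0("column '", col, "' has missing values; run impute_missing() first."))
    }
    if (is.numeric(x)) x <- discretize_numeric(x, numeric_bins)
    x <- as.character(x)
    cats <- lex_sort(unique(x))
    if (length(cats) == 1L) {
      rlang::warn(paste0("feature '", col, "' has a single category ('", cats,
                         "'); its item will be trivially frequent."))
    }
    block <- vapply(cats, function(cc) as.integer(x == cc), integer(length(x)))
    block <- matrix(block, nrow = length(x),
                    dimnames = list(NULL, paste0(col, "=", cats)))
    cols[[col]] <- block
    feats <- c(feats, rep(col, length(cats)))
  }
  m <- do.call(cbind, cols)
  transaction_db(m, item_feature = feats)
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper chaining the four cleaning steps in order: outlier
#' removal (numeric columns, robust z-score), imputation (mean/mode),
#' min-max normalisation, one-hot encoding.
#'
#' @inheritParams remove_outliers
#' @inheritParams impute_missing
#' @inheritParams encode_transactions
#' @param class_column Optional outcome column name; it is excluded from the
#'   encoded items (it drives the feature weights instead). Use
#'   `include_class = TRUE` to mine it as items too.
#' @param include_class Encode the class column as items as well
#'   (default `FALSE`).
#' @return A list with elements `data` (the cleaned tibble, before encoding)
#'   and `db` (the [transaction_db()]).
#' @export
preprocess_registry <- function(data, class_column = NULL, z_threshold = 3,
                                na_tokens = c("", "NA"), numeric_bins = 3,
                                include_class = FALSE) {
  clean <- data |>
    remove_outliers(z_threshold = z_threshold) |>
    impute_missing(na_tokens = na_tokens) |>
    normalize_minmax()
  exclude <- if (!is.null(class_column) && !include_class) class_column else NULL
  list(data = clean,
       db = encode_transactions(clean, numeric_bins = numeric_bins, exclude = exclude))
}
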