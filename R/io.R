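#' Read a raw registry table from CSV
#'
#' RFC-4180 CSV with a header row, UTF-8. Column kinds can be declared in a
#' config (see [read_mining_config()]); undeclared columns fall back to
#' autodetection, with non-numeric columns treated as categorical.
#'
#' @param path CSV file path.
#' @param config Optional config list with a `column_kinds` named list
#'   (`"numeric"` or `"categorical"` per column).
#' @return A tibble.
#' @export
read_registry <- function(path, config = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  kinds <- config$column_kinds
  for (col in names(kinds)) {
    if (!col %in% names(out)) next
    out[[col]] <- if (identical(kinds[[col]], "numeric")) {
      as.numeric(out[[col]])
    } else {
      as.character(out[[col]])
    }
  }
  out
}

item_feature_from_names <- function(items) {
  vapply(items, function(it) {
    parts <- strsplit(it, "=", fixed = TRUE)[[1]]
    if (length(parts) > 1L) parts[1] else it
  }, character(1))
}

#' Write / read a transaction database
#'
#' Two plain-text formats: `"dense"` (0/1 CSV with item-name header) and
#' `"basket"` (one line per record with the names of its present items,
#' comma-separated; names containing commas or quotes are RFC-4180 quoted).
#' On reading, each item's source feature is recovered from the
#' `"<feature>=<category>"` naming convention (items without `=` are their
#' own feature, basket semantics).
#'
#' @param db A [transaction_db()].
#' @param path File path.
#' @param format `"dense"` or `"basket"`.
#' @return `write_transactions()` returns `path` invisibly;
#'   `read_transactions()` returns a [transaction_db()].
#' @export
write_transactions <- function(db, path, format = c("dense", "basket")) {
  format <- match.arg(format)
  stopifnot(inherits(db, "transaction_db"))
  if (format == "dense") {
    readr::write_csv(as_tibble(db), path, progress = FALSE)
  } else {
    quote_item <- function(x) {
      need <- grepl('[",]', x)
      x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
      x
    }
    lines <- vapply(db_baskets(db), function(items) {
      paste(quote_item(items), collapse = ",")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path, format = c("dense", "basket")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df)
    transaction_db(m, item_feature = item_feature_from_names(colnames(m)))
  } else {
    lines <- readLines(path)
    baskets <- lapply(lines, function(l) {
      scan(text = l, what = character(), sep = ",", quote = '"',
           quiet = TRUE, strip.white = FALSE)
    })
    items <- lex_sort(unique(unlist(baskets)))
    m <- matrix(0L, nrow = length(baskets), ncol = length(items),
                dimnames = list(NULL, items))
    for (i in seq_along(baskets)) m[i, baskets[[i]]] <- 1L
    transaction_db(m, item_feature = item_feature_from_names(items))
  }
}

#' Write / read feature weights as a two-column CSV
#'
#' @param weights A [feature_weights()] tibble.
#' @param path File path.
#' @return `write_weights()` returns `path` invisibly; `read_weights()`
#'   returns a `feature_weights` tibble (recomputing `removed` from the
#'   stored threshold, default 0.001).
#' @param threshold Removal threshold applied on read when the file lacks a
#'   `removed` column.
#' @export
write_weights <- function(weights, path) {
  readr::write_csv(
    dplyr::select(weights, "feature", information_gain = "weight"),
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path, threshold = 0.001) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  remove_low_weight_features(
    tibble::tibble(feature = df$feature, weight = df$information_gain),
    threshold = threshold)
}

#' Read a mining configuration file (YAML or JSON)
#'
#' Unknown keys are preserved; missing keys take the package defaults.
#'
#' @param path `.yml`/`.yaml` or `.json` file.
#' @return A named list with at least: `class_column`, `weight_threshold`,
#'   `numeric_bins`, `support_norm`, `min_support_mode`,
#'   `fixed_min_support`, `min_confidence`, `z_threshold`, `na_tokens`,
#'   `seed`, `column_kinds`.
#' @export
read_mining_config <- function(path) {
  defaults <- list(
    class_column = NULL, weight_threshold = 0.001, numeric_bins = 3,
    support_norm = "records", min_support_mode = "mean_of_supports",
    fixed_min_support = NULL, min_confidence = 0.7, z_threshold = 3,
    na_tokens = c("", "NA"), seed = 1L, column_kinds = NULL)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  utils::modifyList(defaults, user %||% list(), keep.null = TRUE)
}

#' JSON run report for a weighted mining result
#'
#' A machine-readable account of a run: configuration echo (including the
#' entropy base the weights were computed in), per-level candidate/survivor
#' counts and automatic thresholds, total pattern count, and optionally
#' timing. With `timing = NULL` the report is a pure function of the input,
#' byte-identical across reruns.
#'
#' @param fit A [mine_weighted()] result.
#' @param timing Optional list (e.g. `list(wall_seconds = ...)`) appended
#'   verbatim.
#' @return `run_report()` returns the report as a list;
#'   `write_run_report()` writes it as JSON and returns `path` invisibly.
#' @export
run_report <- function(fit, timing = NULL) {
  stopifnot(inherits(fit, "weighted_apriori"))
  rep <- list(
    config = fit$config,
    levels = lapply(fit$levels, function(l) list(
      k = l$k, min_support = l$min_support,
      n_candidates = nrow(l$candidates), n_survivors = nrow(l$survivors))),
    n_frequent = nrow(fit$all_frequent),
    frequent = lapply(seq_len(nrow(fit$all_frequent)), function(i) list(
      itemset = fit$all_frequent$itemset[i],
      k = fit$all_frequent$k[i],
      count = fit$all_frequent$count[i],
      hm_weight = fit$all_frequent$hm_weight[i],
      weighted_support = fit$all_frequent$weighted_support[i],
      level_min_support = fit$all_frequent$level_min_support[i]))
  )
  if (!is.null(timing)) rep$timing <- timing
  rep
}

#' @rdname run_report
#' @param path Output JSON path.
#' @export
write_run_report <- function(fit, path, timing = NULL) {
  jsonlite::write_json(run_report(fit, timing = timing), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write frequent itemsets or rules as CSV
#'
#' Flattens list-columns to the canonical `" & "`-joined itemset strings.
#'
#' @param x A frequent-itemsets tibble (e.g. `tidy()` of a fit) or a rules
#'   tibble.
#' @param path Output path.
#' @export
write_itemsets <- function(x, path) {
  flat <- dplyr::mutate(x, dplyr::across(dplyr::where(is.list),
                                         ~ vapply(.x, itemset_key, character(1))))
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}
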