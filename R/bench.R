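# wall time + R-side high-water memory around a closure; memory is the gc
# "max used" delta in bytes, indicative only (hardware/GC dependent)
measure_run <- function(fun) {
  gc(reset = TRUE)
  t0 <- proc.time()[["elapsed"]]
  value <- fun()
  wall <- proc.time()[["elapsed"]] - t0
  g <- gc()
  peak <- sum(g[, "max used"] * c(56, 8))   # Ncells, Vcells sizes in bytes
  list(value = value, wall_seconds = wall, peak_memory_bytes = peak)
}

rendered_bytes <- function(df) {
  if (nrow(df) == 0L) return(0L)
  flat <- dplyr::mutate(df, dplyr::across(dplyr::where(is.list),
                                          ~ vapply(.x, itemset_key, character(1))))
  nchar(readr::format_csv(flat), type = "bytes")
}

#' Compare the weighted miner with the classic baseline on one database
#'
#' Runs the automatic-threshold weighted miner once (its single operating
#' point) and the classic fixed-threshold miner across a grid, collecting
#' the comparison surfaces: pattern and rule counts, median confidence per
#' itemset size, wall time, indicative peak memory and rendered output
#' sizes. Timing and memory are recorded for orientation only — they depend
#' on the host — while the counts are deterministic.
#'
#' @param db A [transaction_db()].
#' @param weights A [feature_weights()] tibble or named item-weight vector.
#' @param grid Ascending thresholds for the classic sweep.
#' @param min_confidence Rule threshold applied to both methods
#'   (default 0.7).
#' @param min_support_mode,support_norm Weighted-miner configuration, see
#'   [mine_weighted()].
#' @param time_budget Seconds allowed per classic threshold.
#' @return An object of class `mining_comparison`: `methods` (one summary
#'   row per method), `grid` (classic sweep tibble), `median_confidence`
#'   (per method and itemset size), `weighted_levels` (per-level automatic
#'   thresholds), `effective_threshold` (the weighted miner's level-1
#'   minimum support, the x-position of its point on classic-style curves)
#'   and `weighted_fit`.
#' @export
compare_methods <- function(db, weights, grid, min_confidence = 0.7,
                            min_support_mode = "mean_of_supports",
                            support_norm = "records", time_budget = 60) {
  stopifnot(inherits(db, "transaction_db"))
  run_w <- measure_run(function() {
    fit <- mine_weighted(db, weights, min_support_mode = min_support_mode,
                         support_norm = support_norm)
    rules <- generate_rules(fit, min_confidence = min_confidence)
    list(fit = fit, rules = rules)
  })
  wfit <- run_w$value$fit
  wrules <- run_w$value$rules
  sweep <- sweep_min_support(db, grid, min_confidence = min_confidence,
                             time_budget = time_budget)
  # classic summary row: the grid threshold closest to the weighted miner's
  # level-1 operating point (or the first grid point when none completed)
  eff <- if (length(wfit$levels) > 0L) wfit$levels[[1]]$min_support else NA_real_
  done <- which(sweep$completed)
  pick <- if (length(done)) done[which.min(abs(sweep$min_support[done] - eff))] else 1L
  run_c <- measure_run(function() {
    fit <- classic_apriori(db, min_support = sweep$min_support[pick])
    rules <- generate_rules(fit, min_confidence = min_confidence)
    list(fit = fit, rules = rules)
  })
  cfit <- run_c$value$fit
  crules <- run_c$value$rules
  methods <- tibble::tibble(
    method = c("weighted", "classic"),
    min_support = c(eff, cfit$min_support),
    n_patterns = c(nrow(wfit$all_frequent), nrow(cfit$frequent)),
    n_rules = c(nrow(wrules), nrow(crules)),
    wall_seconds = c(run_w$wall_seconds, run_c$wall_seconds),
    peak_memory_bytes = c(run_w$peak_memory_bytes, run_c$peak_memory_bytes),
    output_bytes = c(rendered_bytes(wfit$all_frequent) + rendered_bytes(wrules),
                     rendered_bytes(cfit$frequent) + rendered_bytes(crules))
  )
  med <- dplyr::bind_rows(
    dplyr::mutate(median_confidence_by_size(wrules), method = "weighted"),
    dplyr::mutate(median_confidence_by_size(crules), method = "classic")
  ) |> dplyr::select("method", dplyr::everything())
  wl <- tibble::tibble(
    k = vapply(wfit$levels, `[[`, integer(1), "k"),
    min_support = vapply(wfit$levels, `[[`, numeric(1), "min_support"),
    n_candidates = vapply(wfit$levels, function(l) nrow(l$candidates), integer(1)),
    n_survivors = vapply(wfit$levels, function(l) nrow(l$survivors), integer(1))
  )
  structure(list(methods = methods, grid = sweep, median_confidence = med,
                 weighted_levels = wl, effective_threshold = eff,
                 weighted_fit = wfit, min_confidence = min_confidence),
            class = "mining_comparison")
}

#' @export
print.mining_comparison <- function(x, ...) {
  cat("<mining_comparison>\n")
  print(x$methods)
  cat("classic sweep over", nrow(x$grid), "thresholds; weighted operating point at",
      format(x$effective_threshold, digits = 4), "\n")
  invisible(x)
}
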