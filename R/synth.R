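#' Specify a synthetic categorical registry
#'
#' Defines a registry-style table generator: categorical features with fixed
#' marginal category probabilities (plus optionally log-normal numeric
#' features such as treatment cost), a set of planted co-occurring patterns
#' that are activated per record with a given penetration probability, an
#' outcome column driven by pattern membership with label noise, and an
#' optional missing-cell rate. Everything is reproducible from `seed`.
#'
#' @param n_records Number of records to generate.
#' @param features Named list describing the columns. A categorical feature
#'   is a named numeric vector of category probabilities (summing to 1); a
#'   numeric feature is `list(numeric = TRUE, meanlog =, sdlog =)` sampled
#'   from a log-normal.
#' @param planted_patterns List of patterns, each
#'   `list(items = c(<feature> = <category>, ...), penetration = p)` with
#'   `p` in (0, 1]. Each pattern is activated independently per record; an
#'   active pattern forces its feature = category assignments. Patterns that
#'   share a feature are rejected at validation so the ground truth stays
#'   unambiguous.
#' @param class_rule `list(class_name =, active =, inactive =, noise =)`:
#'   the outcome column is `active` when any planted pattern fired and
#'   `inactive` otherwise, then flipped with probability `noise`.
#' @param missing_rate Fraction of feature cells blanked to `NA`, in
#'   [0, 1). The outcome column is never blanked (it is the supervision
#'   signal for the weighting stage).
#' @param seed Integer RNG seed.
#' @return A validated object of class `synth_spec`.
#' @export
synth_spec <- function(n_records, features, planted_patterns = list(),
                       class_rule = list(class_name = "outcome",
                                         active = "case", inactive = "control",
                                         noise = 0.1),
                       missing_rate = 0, seed = 1L) {
  spec <- structure(
    list(n_records = as.integer(n_records), features = features,
         planted_patterns = planted_patterns, class_rule = class_rule,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "synth_spec")
  validate_synth_spec(spec)
}

validate_synth_spec <- function(spec) {
  if (spec$n_records < 1L) abort_wapriori("n_records must be >= 1.")
  if (length(spec$features) == 0L || is.null(names(spec$features))) {
    abort_wapriori("`features` must be a non-empty named list.")
  }
  for (f in names(spec$features)) {
    fs <- spec$features[[f]]
    if (is.list(fs) && isTRUE(fs$numeric)) next
    if (!is.numeric(fs) || is.null(names(fs))) {
      abort_wapriori(paste0("feature '", f, "' must be a named probability vector."))
    }
    if (abs(sum(fs) - 1) > 1e-9) {
      abort_wapriori(paste0("marginals of feature '", f, "' must sum to 1 (got ",
                            format(sum(fs)), ")."))
    }
    if (any(fs < 0)) abort_wapriori(paste0("negative marginal in feature '", f, "'."))
  }
  seen_feats <- character(0)
  for (p in spec$planted_patterns) {
    if (is.null(p$items) || is.null(names(p$items)) || length(p$items) == 0L) {
      abort_wapriori("each planted pattern needs a named `items` vector (feature = category).")
    }
    if (is.null(p$penetration) || p$penetration <= 0 || p$penetration > 1) {
      abort_wapriori("pattern penetration must lie in (0, 1].")
    }
    for (f in names(p$items)) {
      fs <- spec$features[[f]]
      if (is.null(fs)) abort_wapriori(paste0("pattern references unknown feature '", f, "'."))
      if (is.list(fs) && isTRUE(fs$numeric)) {
        abort_wapriori(paste0("pattern cannot plant a category on numeric feature '", f, "'."))
      }
      if (!p$items[[f]] %in% names(fs)) {
        abort_wapriori(paste0("pattern category '", p$items[[f]],
                              "' not among the categories of '", f, "'."))
      }
      if (f %in% seen_feats) {
        abort_wapriori(paste0("planted patterns overlap on feature '", f,
                              "': two patterns could assign it conflicting categories."))
      }
    }
    seen_feats <- c(seen_feats, names(p$items))
  }
  cr <- spec$class_rule
  if (!is.null(cr)) {
    if (is.null(cr$class_name) || is.null(cr$active) || is.null(cr$inactive)) {
      abort_wapriori("class_rule needs `class_name`, `active` and `inactive` labels.")
    }
    if (cr$class_name %in% names(spec$features)) {
      abort_wapriori("class_name clashes with a feature name.")
    }
    noise <- cr$noise %||% 0
    if (noise < 0 || noise >= 0.5) abort_wapriori("class noise must lie in [0, 0.5).")
  }
  if (spec$missing_rate < 0 || spec$missing_rate >= 1) {
    abort_wapriori("missing_rate must lie in [0, 1).")
  }
  spec
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec> ", x$n_records, " records, ", length(x$features),
      " features, ", length(x$planted_patterns), " planted pattern(s), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic registry table from a spec
#'
#' Per record: each planted pattern fires independently with its penetration
#' probability; active patterns force their feature = category assignments;
#' all remaining cells are sampled from the feature marginals (log-normal
#' draws for numeric features); the outcome label follows the class rule
#' with label noise; finally feature cells are blanked at `missing_rate`.
#' The RNG state is saved and restored, so generation is a pure function of
#' the spec.
#'
#' @param spec A [synth_spec()].
#' @return A tibble with one column per feature plus the outcome column.
#'   Ground truth travels in attributes: `planted` (the pattern list) and
#'   `activations` (records x patterns logical matrix); see
#'   [ground_truth()].
#' @export
generate_registry <- function(spec) {
  spec <- validate_synth_spec(spec)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  n <- spec$n_records
  cols <- list()
  for (f in names(spec$features)) {
    fs <- spec$features[[f]]
    cols[[f]] <- if (is.list(fs) && isTRUE(fs$numeric)) {
      stats::rlnorm(n, meanlog = fs$meanlog %||% 0, sdlog = fs$sdlog %||% 1)
    } else {
      sample(names(fs), n, replace = TRUE, prob = fs)
    }
  }
  n_pat <- length(spec$planted_patterns)
  act <- matrix(FALSE, nrow = n, ncol = max(n_pat, 0L))
  if (n_pat > 0L) {
    for (j in seq_len(n_pat)) {
      p <- spec$planted_patterns[[j]]
      act[, j] <- stats::runif(n) < p$penetration
      for (f in names(p$items)) {
        cols[[f]][act[, j]] <- p$items[[f]]
      }
    }
  }
  cr <- spec$class_rule
  if (!is.null(cr)) {
    any_active <- if (n_pat > 0L) rowSums(act) > 0L else rep(FALSE, n)
    label <- ifelse(any_active, cr$active, cr$inactive)
    noise <- cr$noise %||% 0
    if (noise > 0) {
      flip <- stats::runif(n) < noise
      label[flip] <- ifelse(label[flip] == cr$active, cr$inactive, cr$active)
    }
    cols[[cr$class_name]] <- label
  }
  if (spec$missing_rate > 0) {
    for (f in names(spec$features)) {
      blank <- stats::runif(n) < spec$missing_rate
      cols[[f]][blank] <- NA
    }
  }
  out <- tibble::as_tibble(cols)
  attr(out, "planted") <- spec$planted_patterns
  attr(out, "activations") <- act
  out
}

#' Ground truth of a generated registry
#'
#' @param data A tibble from [generate_registry()].
#' @return A list: `planted` (pattern list) and `activations`
#'   (records x patterns logical matrix).
#' @export
ground_truth <- function(data) {
  list(planted = attr(data, "planted"), activations = attr(data, "activations"))
}

#' Default trauma-registry-like generator spec
#'
#' A ready-made [synth_spec()] that mirrors the schema of a hospital trauma
#' registry: 11 features (age group, conveyance to the emergency department,
#' birthplace, total expenditures as a numeric cost, insurance type, days
#' admitted, sex, transport/external-cause codes, occupation, injured body
#' region, education) plus a discharge-state outcome column. One 3-item
#' pattern — elderly age, a stay of three days and more, a head injury — is
#' planted with the given penetration, and the discharge state follows
#' pattern membership with 10% label noise, so the information-gain stage
#' has a real signal to find.
#'
#' Marginal probabilities are fixed, field-plausible choices (e.g. male
#' majority, motorcycle accidents as the dominant transport mechanism).
#'
#' @param n_records Number of records (default 2000).
#' @param penetration Activation probability of the planted pattern
#'   (default 0.8).
#' @param missing_rate Fraction of feature cells blanked (default 0).
#' @param seed RNG seed (default 1).
#' @return A `synth_spec`.
#' @export
table2_spec <- function(n_records = 2000, penetration = 0.8,
                        missing_rate = 0, seed = 1L) {
  features <- list(
    "Age" = c("child" = 0.12, "teenager" = 0.15, "young" = 0.33,
              "middle-aged" = 0.22, "elderly" = 0.18),
    "Type of conveyance carrying to emergency" =
      c("ambulance" = 0.45, "taxi" = 0.20, "personal vehicle" = 0.35),
    "Place birth" = c("city" = 0.70, "village" = 0.30),
    "Total expenditures" = list(numeric = TRUE, meanlog = 15, sdlog = 1),
    "Type of insurance" = c("treatment services" = 0.25, "social security" = 0.40,
                            "military" = 0.05, "bank" = 0.03, "free" = 0.12,
                            "others" = 0.15),
    "Number of days admitted" = c("One day" = 0.45, "two days" = 0.25,
                                  "three days and more" = 0.30),
    "Sex" = c("male" = 0.72, "female" = 0.28),
    "ICD-injuries" = c(
      "Pedestrian injured in transport accident" = 0.18,
      "Pedal cycle rider injured in transport accident" = 0.05,
      "Motorcycle rider injured in transport accident" = 0.38,
      "Car occupant injured in transport accident" = 0.22,
      "Water transport accidents" = 0.01,
      "Slipping, tripping, stumbling and falls" = 0.14,
      "Exposure to electric current, radiation and extreme ambient air temperature and pressure" = 0.02),
    "Occupation" = c("child" = 0.08, "staff" = 0.07, "worker" = 0.20,
                     "farmer" = 0.08, "unemployed" = 0.10, "students" = 0.18,
                     "businessmen" = 0.09, "housewives" = 0.15, "others job" = 0.05),
    "ICD-external causes" = c(
      "Injuries to the head" = 0.25,
      "Injuries to the abdomen, lower back, lumbar spine, pelvis and external genitals" = 0.10,
      "Injuries to the shoulder and upper arm" = 0.12,
      "Injuries to the elbow and forearm" = 0.10,
      "Injuries to the wrist, hand and fingers" = 0.12,
      "Injuries to the hip and thigh" = 0.08,
      "Injuries to the knee and lower leg" = 0.13,
      "Injuries to the ankle and foot" = 0.10),
    "Education" = c("child" = 0.10, "illiterate" = 0.12, "school" = 0.28,
                    "high school" = 0.35, "after diploma" = 0.15)
  )
  synth_spec(
    n_records = n_records,
    features = features,
    planted_patterns = list(list(
      items = c("Age" = "elderly",
                "Number of days admitted" = "three days and more",
                "ICD-external causes" = "Injuries to the head"),
      penetration = penetration)),
    class_rule = list(class_name = "State of discharge",
                      active = "non-improvement", inactive = "improvement",
                      noise = 0.1),
    missing_rate = missing_rate,
    seed = seed
  )
}
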