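test_that("weighted confidence matches hand-computed ratios", {
  # all weights 1: reduces to classic confidence count(AB)/count(A) = 3/4
  m <- matrix(0L, 8, 2, dimnames = list(NULL, c("A", "B")))
  m[1:4, "A"] <- 1L
  m[1:3, "B"] <- 1L
  db <- transaction_db(m)
  expect_equal(weighted_confidence(c("A", "B"), "A", db, c(A = 1, B = 1)), 0.75)

  # spec-style derived case: N = 20, count(A) = 10, count(AB) = 5,
  # weights 0.2 / 0.6, HM = 0.3 -> conf = (5 * 0.3) / (10 * 0.2) = 0.75
  m2 <- matrix(0L, 20, 2, dimnames = list(NULL, c("a", "b")))
  m2[1:10, "a"] <- 1L
  m2[1:5, "b"] <- 1L
  db2 <- transaction_db(m2)
  expect_equal(harmonic_mean(c(0.2, 0.6)), 0.3)
  expect_equal(weighted_confidence(c("a", "b"), "a", db2, c(a = 0.2, b = 0.6)),
               0.75)

  # empty consequent is forbidden
  expect_error(weighted_confidence(c("a", "b"), c("a", "b"), db2,
                                   c(a = 0.2, b = 0.6)), "proper subset")
  # zero-support antecedent is undefined
  m3 <- matrix(c(0L, 0L, 1L, 1L), 2, dimnames = list(NULL, c("z", "w")))
  expect_error(weighted_confidence(c("z", "w"), "z", transaction_db(m3),
                                   c(z = 1, w = 1)), "zero support")
})

test_that("rule generation enumerates antecedents and filters by confidence", {
  # craft a db where {A, B} is frequent, conf(A->B) = 0.8, conf(B->A) = 0.5
  m <- matrix(0L, 10, 2, dimnames = list(NULL, c("A", "B")))
  m[1:5, "A"] <- 1L
  m[c(1:4, 6:9), "B"] <- 1L
  db <- transaction_db(m)
  fit <- mine_weighted(db, c(A = 1, B = 1), min_support_mode = "fixed",
                       fixed_min_support = 0.4)
  expect_true("A & B" %in% fit$all_frequent$itemset)
  rules <- generate_rules(fit, min_confidence = 0.7)
  expect_equal(nrow(rules), 1L)
  expect_equal(rules$antecedent, "A")
  expect_equal(rules$consequent, "B")
  expect_equal(rules$weighted_confidence, 0.8)

  # min_confidence = 0 gives all 2^k - 2 antecedent splits per itemset
  all_rules <- generate_rules(fit, min_confidence = 0)
  expected <- sum(2^fit$all_frequent$k[fit$all_frequent$k >= 2] - 2)
  expect_equal(nrow(all_rules), expected)

  # no itemsets of size >= 2: empty rule table
  lone <- mine_weighted(transaction_db(matrix(c(1L, 0L, 0L, 1L), 2,
                          dimnames = list(NULL, c("x", "y")))),
                        c(x = 1, y = 1))
  expect_equal(nrow(generate_rules(lone, min_confidence = 0)), 0L)

  expect_error(generate_rules(fit, min_confidence = -0.1), "non-negative")
})

test_that("rule completeness at zero confidence holds on random weighted runs", {
  for (seed in c(801, 802)) {
    m <- random_mat(60, 7, seed = seed)
    db <- transaction_db(m)
    w <- random_item_weights(colnames(m), seed = seed + 1)
    fit <- mine_weighted(db, w)
    rules <- suppressMessages(generate_rules(fit, min_confidence = 0))
    expected <- sum(2^fit$all_frequent$k[fit$all_frequent$k >= 2] - 2)
    expect_equal(nrow(rules), expected)
    # every rule's union is a mined frequent itemset
    unions <- mapply(function(a, cns) {
      paste(sort(c(split_itemset(a), split_itemset(cns)), method = "radix"),
            collapse = " & ")
    }, rules$antecedent, rules$consequent)
    expect_true(all(unions %in% fit$all_frequent$itemset))
  }
})

test_that("equal weights keep confidences in [0, 1] and equal to count ratios", {
  m <- random_mat(70, 8, seed = 901)
  db <- transaction_db(m)
  w1 <- stats::setNames(rep(1, 8), colnames(m))
  fit <- mine_weighted(db, w1, min_support_mode = "fixed", fixed_min_support = 0.25)
  rules <- generate_rules(fit, min_confidence = 0)
  expect_true(all(rules$weighted_confidence >= 0 & rules$weighted_confidence <= 1))
  for (i in seq_len(nrow(rules))) {
    a <- split_itemset(rules$antecedent[i])
    u <- sort(c(a, split_itemset(rules$consequent[i])), method = "radix")
    expect_equal(rules$weighted_confidence[i],
                 oracle_count(m, u) / oracle_count(m, a))
  }
})

test_that("weighted and classic rules coincide under unit weights", {
  m <- random_mat(50, 7, seed = 1001)
  db <- transaction_db(m)
  w1 <- stats::setNames(rep(1, 7), colnames(m))
  th <- 0.3
  wfit <- mine_weighted(db, w1, min_support_mode = "fixed", fixed_min_support = th)
  cfit <- classic_apriori(db, min_support = th)
  for (conf in c(0, 0.5, 0.8)) {
    expect_equal(rule_keys(generate_rules(wfit, min_confidence = conf)),
                 rule_keys(generate_rules(cfit, min_confidence = conf)))
  }
})

test_that("median confidence by size matches hand-computed medians", {
  rules <- tibble::tibble(
    antecedent = letters[1:6], consequent = LETTERS[1:6],
    union_size = c(4L, 4L, 7L, 4L, 5L, 5L),
    count = 1L, weighted_support = 0.1,
    weighted_confidence = c(0.2, 0.8, 0.9, 0.5, 0.1, 0.5))
  med <- median_confidence_by_size(rules)
  # size 4: median(0.2, 0.8, 0.5) = 0.5; size 5: mean of central pair = 0.3
  expect_equal(med$median_confidence[med$union_size == 4], 0.5)
  expect_equal(med$median_confidence[med$union_size == 5], 0.3)
  expect_equal(med$median_confidence[med$union_size == 7], 0.9)
  # two-element median is the mean of the pair
  two <- median_confidence_by_size(rules[1:2, ])
  expect_equal(two$median_confidence, 0.5)
  # empty input gives an empty, well-formed table
  expect_equal(nrow(median_confidence_by_size(rules[0, ])), 0L)
})

test_that("a notice is emitted when weighted confidence exceeds 1", {
  # high-weight consequent item pushes the union's harmonic mean above the
  # antecedent's singleton weight
  m <- matrix(0L, 10, 2, dimnames = list(NULL, c("lo", "hi")))
  m[1:6, "lo"] <- 1L
  m[1:6, "hi"] <- 1L
  db <- transaction_db(m)
  w <- c(lo = 0.1, hi = 2)
  fit <- mine_weighted(db, w, min_support_mode = "fixed", fixed_min_support = 0.01)
  expect_message(rules <- generate_rules(fit, min_confidence = 0), "confidence > 1")
  expect_gt(max(rules$weighted_confidence), 1)
})
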