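# small fixed database used across several blocks:
# 10 records over items A, B with known counts
fixed_db <- function(countA = 6, countB = 4, n = 10) {
  m <- matrix(0L, nrow = n, ncol = 2, dimnames = list(NULL, c("A", "B")))
  m[seq_len(countA), "A"] <- 1L
  m[seq_len(countB), "B"] <- 1L
  transaction_db(m)
}

test_that("candidate 1-itemsets carry counts and weighted supports", {
  db <- fixed_db()
  c1 <- create_c1(db, c(A = 1, B = 1))
  expect_equal(c1$itemset, c("A", "B"))
  expect_equal(c1$count, c(6L, 4L))
  expect_equal(c1$weighted_support, c(0.6, 0.4))

  # weight 0.5 scales the support: 4 * 0.5 / 10
  c1w <- create_c1(db, c(A = 1, B = 0.5))
  expect_equal(c1w$weighted_support[c1w$itemset == "B"], 0.2)

  # items of removed features never appear
  d <- data.frame(a = c("x", "y"), b = c("u", "v"))
  dbf <- encode_transactions(d)
  w <- tibble::tibble(feature = c("a", "b"), weight = c(0.5, 0.00001),
                      removed = c(FALSE, TRUE))
  expect_setequal(create_c1(dbf, w)$itemset, c("a=x", "a=y"))
})

test_that("weighted support follows count x harmonic mean / N", {
  db <- fixed_db(countA = 6, countB = 4)
  # make A and B co-occur in exactly 4 records
  expect_equal(weighted_support(c("A", "B"), db, c(A = 0.5, B = 0.5)),
               4 * 0.5 / 10)
  # equal weights of 1 reduce to classic support
  expect_equal(weighted_support("A", db, c(A = 1, B = 1)), 0.6)
  # absent itemset has zero support
  m <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(weighted_support(c("A", "B"), transaction_db(m), c(A = 1, B = 1)), 0)
  # unweighted item errors
  expect_error(weighted_support("Z", db, c(A = 1, B = 1)), "no weight")
})

test_that("the automatic level threshold has both documented modes", {
  expect_equal(level_min_support(0.37), 0.37)                      # mean of one
  expect_equal(level_min_support(c(0.2, 0.4)), 0.3)                # arithmetic mean
  expect_equal(level_min_support(c(0.2, 0.4), n_records = 10,
                                 mode = "literal_eq6"), 0.06)      # sum / N
  expect_error(level_min_support(numeric(0)), "no candidates")
  expect_error(level_min_support(c(0.1), mode = "literal_eq6"), "n_records")
})

test_that("scan_level prunes below the level threshold inclusively", {
  db <- fixed_db(countA = 6, countB = 4)   # supports 0.6 and 0.4 at weight 1
  # rescale to a 0.2 / 0.4 support pair via weights
  lvl <- scan_level(db, list("A", "B"), c(A = 1 / 3, B = 1))
  expect_equal(lvl$candidates$weighted_support, c(0.2, 0.4))
  expect_equal(lvl$min_support, 0.3)
  expect_equal(lvl$survivors$itemset, "B")

  # equal supports: everything survives (inclusive >=)
  db2 <- fixed_db(countA = 5, countB = 5)
  lvl2 <- scan_level(db2, list("A", "B"), c(A = 1, B = 1))
  expect_equal(lvl2$min_support, 0.5)
  expect_setequal(lvl2$survivors$itemset, c("A", "B"))

  # a single candidate always survives in mean mode
  lvl3 <- scan_level(db, list("A"), c(A = 1, B = 1))
  expect_equal(lvl3$survivors$itemset, "A")
})

test_that("apriori_gen joins on shared prefixes and prunes by subsets", {
  expect_equal(apriori_gen(list("A", "B")), list(c("A", "B")))
  expect_equal(apriori_gen(list(c("A", "B"), c("A", "C"), c("B", "C"))),
               list(c("A", "B", "C")))
  # {B, C} is not frequent, so {A, B, C} is pruned
  expect_equal(apriori_gen(list(c("A", "B"), c("A", "C"))), list())
  expect_equal(apriori_gen(list("A")), list())
})

test_that("mining terminates and reports levels faithfully", {
  set.seed(73)
  m <- random_mat(40, 6, seed = 73)
  db <- transaction_db(m)
  w <- random_item_weights(colnames(m), seed = 74)
  fit <- mine_weighted(db, w)
  last <- fit$levels[[length(fit$levels)]]
  expect_true(nrow(last$survivors) == 0L ||
                length(apriori_gen(last$survivors$items)) == 0L)
  # an item present in every record is frequent at level 1 under equal weights
  m2 <- cbind(m, always = 1L)
  fit2 <- mine_weighted(transaction_db(m2),
                        stats::setNames(rep(1, 7), colnames(m2)))
  expect_true("always" %in% fit2$levels[[1]]$survivors$itemset)
})

test_that("every level matches an independent brute-force replay", {
  for (seed in c(101, 102, 103)) {
    m <- random_mat(50, 7, seed = seed)
    w <- random_item_weights(colnames(m), seed = seed + 500)
    db <- transaction_db(m)
    for (mode in c("mean_of_supports", "literal_eq6")) {
      fit <- mine_weighted(db, w, min_support_mode = mode)
      orc <- oracle_levels(m, w, mode = mode)
      expect_equal(length(fit$levels), length(orc))
      for (k in seq_along(orc)) {
        expect_setequal(fit$levels[[k]]$candidates$itemset, orc[[k]]$candidates)
        expect_equal(fit$levels[[k]]$min_support, orc[[k]]$min_support,
                     tolerance = 1e-12)
        expect_setequal(fit$levels[[k]]$survivors$itemset, orc[[k]]$survivors)
      }
    }
  }
})

test_that("with unit weights and a fixed threshold the weighted miner
           reduces to classic Apriori", {
  for (seed in c(201, 202)) {
    m <- random_mat(60, 8, seed = seed)
    db <- transaction_db(m)
    w1 <- stats::setNames(rep(1, 8), colnames(m))
    th <- 0.3
    fit <- mine_weighted(db, w1, min_support_mode = "fixed",
                         fixed_min_support = th)
    base <- classic_apriori(db, min_support = th)
    expect_setequal(fit$all_frequent$itemset, base$frequent$itemset)
  }
})

test_that("survivor counts are monotone along subset chains and results
           are deterministic", {
  m <- random_mat(80, 8, seed = 301)
  db <- transaction_db(m)
  w <- random_item_weights(colnames(m), seed = 302)
  fit1 <- mine_weighted(db, w)
  fit2 <- mine_weighted(db, w)
  expect_identical(tidy(fit1), tidy(fit2))
  r1 <- run_report(fit1)
  r2 <- run_report(fit2)
  expect_identical(jsonlite::toJSON(r1, auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(r2, auto_unbox = TRUE, digits = NA))
  # raw counts never grow when items are added
  freq <- fit1$all_frequent
  for (i in seq_len(nrow(freq))) {
    for (j in seq_len(nrow(freq))) {
      if (i == j) next
      if (all(freq$items[[i]] %in% freq$items[[j]])) {
        expect_gte(freq$count[i], freq$count[j])
      }
    }
  }
})

test_that("survivors are sorted by weighted support with lexicographic ties", {
  m <- random_mat(60, 7, seed = 401)
  db <- transaction_db(m)
  w <- random_item_weights(colnames(m), seed = 402)
  fit <- mine_weighted(db, w)
  for (lvl in fit$levels) {
    s <- lvl$survivors
    if (nrow(s) < 2L) next
    expect_true(all(diff(s$weighted_support) <= 1e-15))
    ties <- which(diff(s$weighted_support) == 0)
    for (t in ties) expect_true(s$itemset[t] < s$itemset[t + 1])
  }
})

test_that("items of removed features never reach the mined itemsets", {
  spec <- table2_spec(n_records = 400, seed = 9)
  d <- generate_registry(spec)
  pp <- preprocess_registry(d, class_column = "State of discharge")
  w <- feature_weights(pp$data, "State of discharge", threshold = 0.02)
  expect_true(any(w$removed))   # 0.02 bits removes the noise features here
  fit <- mine_weighted(pp$db, w)
  mined_feats <- unique(pp$db$item_feature[unlist(fit$all_frequent$items)])
  expect_false(any(mined_feats %in% w$feature[w$removed]))
})
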