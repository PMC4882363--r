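itemset_key_counts <- function(fi) {
  stats::setNames(fi$count,
                  vapply(fi$items, paste, character(1), collapse = ITEM_SEP))
}

test_that("frequent itemsets match hand-enumerated supports", {
  tx <- list(c("a", "b"), c("a", "b", "c"), c("a", "c"))
  fi <- frequent_itemsets(tx, 0.5, 3)
  got <- itemset_key_counts(fi)
  expected <- stats::setNames(
    c(3L, 2L, 2L, 2L, 2L),
    c("a", "b", "c", paste("a", "b", sep = ITEM_SEP),
      paste("a", "c", sep = ITEM_SEP)))
  expect_mapequal(as.list(got), as.list(expected))
  expect_equal(fi$support, fi$count / 3)

  only_a <- frequent_itemsets(tx, 1.0, 3)
  expect_equal(itemset_key_counts(only_a), c(a = 3L))

  expect_equal(nrow(frequent_itemsets(tx, 1.0, 1)), 1L)
  expect_error(frequent_itemsets(list(), 0.5, 2), "transactions")
})

test_that("anti-monotonicity holds on mined itemsets", {
  tx <- make_labeled_txns(12, 8, 0.5, seed = 3)
  fi <- frequent_itemsets(tx, 2 / 12, 4)
  counts <- itemset_key_counts(fi)
  for (i in seq_len(nrow(fi))) {
    s <- fi$items[[i]]
    if (length(s) < 2L) next
    for (drop in seq_along(s)) {
      sub <- paste(s[-drop], collapse = ITEM_SEP)
      expect_true(sub %in% names(counts))
      expect_gte(counts[[sub]], fi$count[[i]])
    }
  }
})

test_that("miner and rule generator match brute-force enumeration on random baskets", {
  mismatches <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    tx <- make_labeled_txns(sample(4:12, 1), sample(4:9, 1),
                            runif(1, 0.25, 0.7), seed = seed)
    min_s <- sample(c(1, 2, 3), 1) / length(tx)
    max_l <- sample(2:4, 1)
    min_c <- sample(c(0.5, 0.75, 0.9), 1)

    fi <- frequent_itemsets(tx, min_s, max_l)
    expected <- brute_itemsets(tx, min_s, max_l)
    got <- itemset_key_counts(fi)
    expect_mapequal(as.list(got), as.list(expected))

    rs <- generate_rules(fi, min_confidence = min_c)
    got_rules <- ruleset_rules(rs)[c("lhs_key", "rhs", "support",
                                     "confidence", "lift")]
    got_rules <- got_rules[order(got_rules$rhs, got_rules$lhs_key), ,
                           drop = FALSE]
    rownames(got_rules) <- NULL
    exp_rules <- brute_rules(tx, min_s, max_l, min_c)
    rownames(exp_rules) <- NULL
    if (!isTRUE(all.equal(got_rules, exp_rules, tolerance = 1e-14))) {
      mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("rule statistics follow the hand-computed example", {
  tx <- list(c("a", "CAT2"), c("a", "CAT2"), c("a", "CAT3"))
  rs <- generate_rules(frequent_itemsets(tx, 0.01, 3), min_confidence = 0.6)
  r <- ruleset_rules(rs)
  expect_equal(nrow(r), 1L)
  expect_equal(r$rhs, "CAT2")
  expect_equal(r$support, 2 / 3)
  expect_equal(r$confidence, 2 / 3)
  expect_equal(r$lift, 1.0)  # no better than chance
})

test_that("a perfectly determining feature survives min_confidence = 1", {
  tx <- list(c("a", "CAT2"), c("a", "CAT2"), c("b", "CAT3"))
  rs <- generate_rules(frequent_itemsets(tx, 0.01, 2), min_confidence = 1.0)
  r <- ruleset_rules(rs)
  expect_true(any(r$lhs_key == "a" & r$rhs == "CAT2" & r$confidence == 1.0))
})

test_that("confidence and lift identities hold to 1e-12 for every rule", {
  tx <- make_labeled_txns(14, 9, 0.5, seed = 5)
  fi <- frequent_itemsets(tx, 1 / 14, 4)
  rs <- generate_rules(fi, min_confidence = 0.5)
  r <- ruleset_rules(rs)
  counts <- itemset_key_counts(fi)
  n <- length(tx)
  for (i in seq_len(nrow(r))) {
    joint <- counts[[paste(sort(c(r$lhs[[i]], r$rhs[[i]])),
                           collapse = ITEM_SEP)]]
    lhs_ct <- counts[[r$lhs_key[[i]]]]
    rhs_ct <- counts[[r$rhs[[i]]]]
    expect_equal(r$confidence[[i]], joint / lhs_ct, tolerance = 1e-12)
    expect_equal(r$lift[[i]], (joint / lhs_ct) / (rhs_ct / n),
                 tolerance = 1e-12)
    expect_lte(r$support[[i]], r$confidence[[i]])
  }
})

test_that("transactions carry exactly one category item and honour the count filter", {
  rec <- hazard_records(c("a", "b", "c"), c("c1ccccc1", "Cc1ccccc1", "CCCC"),
                        c(5, 5, 50))
  fps <- fingerprint_all(stats::setNames(rec$smiles, rec$id))
  txns <- build_transactions(rec, fps)
  expect_s3_class(txns, "tox_transactions")
  n_cat <- vapply(txns$items, function(it)
    sum(it %in% paste0("CAT", 1:4)), integer(1))
  expect_equal(n_cat, rep(1L, 3))
  # feature in all chemicals is in all transactions
  common <- Reduce(intersect, lapply(fps, `[[`, "features"))
  if (length(common) > 0) {
    expect_true(all(vapply(txns$items, function(it) common[[1]] %in% it,
                           logical(1))))
  }
  # a feature unique to one chemical disappears under min_count = 2
  uniq <- setdiff(fps[["c"]]$features,
                  union(fps[["a"]]$features, fps[["b"]]$features))
  expect_gt(length(uniq), 0L)
  t2 <- build_transactions(rec, fps, min_count = 2L)
  expect_false(any(vapply(t2$items, function(it) uniq[[1]] %in% it,
                          logical(1))))
  expect_error(build_transactions(rec, fps["a"]), "missing fingerprint")
})

test_that("rule minimisation removes uninformative antecedent items transitively", {
  # x determines CAT2; y, z always co-occur with x -> equal statistics chain
  tx <- list(c("x", "y", "z", "CAT2"), c("x", "y", "z", "CAT2"),
             c("w", "CAT3"))
  rs <- generate_rules(frequent_itemsets(tx, 0.01, 4), min_confidence = 0.5)
  r <- ruleset_rules(rs)
  long <- r[r$size == 3 & r$rhs == "CAT2", , drop = FALSE]
  expect_equal(nrow(long), 1L)
  m <- minimize_rule(long, rs)
  expect_equal(m$lhs[[1]], "x")
  mid <- r[r$lhs_key == paste("x", "y", sep = ITEM_SEP), , drop = FALSE]
  expect_equal(minimize_rule(mid, rs)$lhs[[1]], "x")
  # idempotence and fixed point
  expect_identical(minimize_rule(m, rs), m)
  solo <- r[r$lhs_key == "w", , drop = FALSE]
  expect_identical(minimize_rule(solo, rs)$lhs[[1]], "w")
  # minimize_rules maps every rule to a valid row
  idx <- minimize_rules(rs)
  expect_true(all(idx >= 1 & idx <= nrow(r)))
  expect_identical(idx[idx], idx)  # idempotent as a map
})

test_that("top_rules orders by lift, confidence, antecedent size, then key", {
  tx <- c(rep(list(c("p", "CAT2")), 4), list(c("p", "CAT3")),
          rep(list(c("q", "r", "CAT3")), 3))
  rs <- generate_rules(frequent_itemsets(tx, 0.01, 3), min_confidence = 0.5)
  t3 <- top_rules(rs, "CAT3")
  expect_gt(nrow(t3), 1L)
  expect_true(all(diff(t3$lift) <= 1e-12))
  ties <- which(abs(diff(t3$lift)) < 1e-12)
  for (i in ties) expect_gte(t3$confidence[i], t3$confidence[i + 1] - 1e-12)
  expect_equal(nrow(top_rules(rs, "CAT1")), 0L)
})

test_that("rule sets and baskets round-trip through their file formats", {
  tx <- make_labeled_txns(10, 6, 0.5, seed = 9)
  rs <- generate_rules(frequent_itemsets(tx, 0.1, 3), min_confidence = 0.6)
  path <- withr::local_tempfile(fileext = ".json")
  write_ruleset_json(rs, path)
  back <- read_ruleset_json(path)
  keep <- c("lhs", "rhs", "size", "rule_count", "lhs_count", "rhs_count",
            "support", "confidence", "lift", "lhs_key")
  expect_identical(ruleset_rules(rs)[keep], ruleset_rules(back)[keep])
  expect_equal(back$n_transactions, rs$n_transactions)
  expect_equal(back$params$min_confidence, rs$params$min_confidence)

  rec <- hazard_records("a", "CC", 5)
  fps <- fingerprint_all(c(a = "CC"))
  txns <- build_transactions(rec, fps)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_basket_csv(txns, csv)
  got <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(got$id, "a")
  expect_true(grepl("CAT2", got$items))
  expect_true(grepl(";", got$items))
})
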