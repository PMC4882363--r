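# A small engineered basket set giving two rules with known statistics:
#   {x,y} => CAT2 with confidence 0.8   (4 of 5 x,y baskets are CAT2)
#   {z}   => CAT3 with confidence 0.9   (9 of 10 z baskets are CAT3)
classify_fixture <- function() {
  tx <- c(rep(list(c("x", "y", "CAT2")), 4), list(c("x", "y", "CAT3")),
          rep(list(c("z", "CAT3")), 9), list(c("z", "CAT2")))
  generate_rules(frequent_itemsets(tx, 1 / 15, 3), min_confidence = 0.6)
}

test_that("rule prediction picks the highest-confidence matching rule", {
  rs <- classify_fixture()
  hit <- predict_by_rules(c("x", "y", "z"), rs)
  expect_equal(hit$category, "CAT3")
  expect_equal(hit$confidence, 0.9)
  expect_null(predict_by_rules("w", rs))
})

test_that("confidence ties break by lift, then by the more hazardous category", {
  # two perfect rules; CAT2 (more hazardous) must win a full tie
  tx <- c(rep(list(c("u", "CAT2")), 2), rep(list(c("v", "CAT3")), 2))
  rs <- generate_rules(frequent_itemsets(tx, 0.01, 2), min_confidence = 0.5)
  hit <- predict_by_rules(c("u", "v"), rs)
  expect_equal(hit$confidence, 1.0)
  expect_equal(hit$category, "CAT2")
})

test_that("the printed CAT2 toxicophore features match as a rule antecedent", {
  f1 <- render_feature(c("C", 2, 1), c("C", 2, 1), 3)
  f2 <- render_feature(c("O", 1, 1), c("O", 1, 1), 6)
  tx <- c(rep(list(c(f1, f2, "CAT2")), 3), list(c(f1, "CAT3")))
  rs <- generate_rules(frequent_itemsets(tx, 0.01, 3), min_confidence = 0.75)
  hit <- predict_by_rules(c(f1, f2), rs)
  expect_equal(hit$category, "CAT2")
})

test_that("nearest neighbour minimises Tanimoto distance with stated tie-breaks", {
  nn <- nearest_neighbor(c("x", "y"), list(A = c("x", "y"), B = c("u", "v")))
  expect_equal(nn$id, "A"); expect_equal(nn$distance, 0.0)

  nn2 <- nearest_neighbor(c("x", "y"), list(A = "x", B = c("x", "y", "z")))
  expect_equal(nn2$id, "B")
  expect_equal(nn2$distance, 1 / 3)

  # identical distances -> lexicographically smaller id
  nn3 <- nearest_neighbor("x", list(B = c("x", "b"), A = c("x", "a")))
  expect_equal(nn3$id, "A")

  expect_error(nearest_neighbor(character(0), list(A = character(0))),
               "undefined")
})

test_that("prediction falls back to the surrogate's Apriori-predicted category", {
  rs <- classify_fixture()
  training <- list(t1 = c("x", "y"), t2 = c("z", "q"), t3 = c("w", "q"))
  train_pred <- c(t1 = "CAT2", t2 = "CAT3", t3 = NA)

  p <- predict_chemical(new_fp("q1", c("x", "y")), rs, training, train_pred)
  expect_equal(p$mode, "rule"); expect_equal(p$category, "CAT2")

  # no rule matches {z-less query}; nearest rule-covered neighbour decides
  p2 <- predict_chemical(new_fp("q2", c("q", "w")), rs, training, train_pred)
  expect_equal(p2$mode, "surrogate")
  # t3 is nearest but rule-uncovered, so it is skipped; t2 carries CAT3
  expect_equal(p2$neighbor, "t2")
  expect_equal(p2$category, "CAT3")

  # no training chemical rule-covered -> unclassifiable
  p3 <- predict_chemical(new_fp("q3", "q"), rs, training,
                         c(t1 = NA, t2 = NA, t3 = NA))
  expect_equal(p3$category, "unclassifiable")
  expect_equal(p3$mode, "none")

  # empty query fingerprint -> unclassifiable
  p4 <- predict_chemical(new_fp("q4", character(0)), rs, training, train_pred)
  expect_equal(p4$category, "unclassifiable")
})

test_that("surrogate choice ignores rule-uncovered chemicals farther than the pick", {
  rs <- classify_fixture()
  training <- list(t1 = c("a", "b"), t2 = c("a", "c"))
  train_pred <- c(t1 = "CAT2", t2 = "CAT2")
  base <- predict_chemical(new_fp("q", c("a", "b")), rs, training, train_pred)
  # add an uncovered chemical farther away than the selected neighbour
  training2 <- c(training, list(t9 = c("d", "e")))
  train_pred2 <- c(train_pred, t9 = NA)
  with_extra <- predict_chemical(new_fp("q", c("a", "b")), rs, training2,
                                 train_pred2)
  expect_identical(base[c("category", "mode", "neighbor", "distance")],
                   with_extra[c("category", "mode", "neighbor", "distance")])
})

test_that("rule mode never yields categories the rule set cannot express", {
  rs <- classify_fixture()  # only CAT2/CAT3 rules, like sparse real data
  expect_setequal(unique(ruleset_rules(rs)$rhs), c("CAT2", "CAT3"))
  set.seed(21)
  pool <- c("x", "y", "z", "w", "q")
  for (i in 1:25) {
    fp <- sample(pool, sample(1:4, 1))
    hit <- predict_by_rules(fp, rs)
    if (!is.null(hit)) expect_true(hit$category %in% c("CAT2", "CAT3"))
  }
})

test_that("prediction is deterministic for identical model and query", {
  rs <- classify_fixture()
  training <- list(t1 = c("x", "y"), t2 = c("z", "q"))
  train_pred <- c(t1 = "CAT2", t2 = "CAT3")
  p1 <- predict_chemical(new_fp("q", c("q")), rs, training, train_pred)
  p2 <- predict_chemical(new_fp("q", c("q")), rs, training, train_pred)
  expect_identical(p1, p2)
})
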