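test_that("reported percentages round half up to one decimal", {
  expect_equal(round_half_up(86.9565), 87.0)
  expect_equal(round_half_up(80.645), 80.6)
  expect_equal(round_half_up(81.25), 81.3)  # ties go up, unlike round()
  expect_equal(round_half_up(63.157), 63.2)
  expect_equal(round_half_up(c(67.74, 62.5)), c(67.7, 62.5))
})

test_that("the 2x2 table counts positives and negatives correctly", {
  t <- build_2x2(c("CAT1", "CAT2A", "NO_CAT", "NO_CAT"),
                 c("irritant", "irritant", "non_irritant", "non_irritant"))
  expect_identical(c(t$tp, t$fn, t$fp, t$tn), c(2L, 0L, 0L, 2L))

  t1 <- build_2x2("CAT2B", "non_irritant")
  expect_identical(c(t1$tp, t1$fn, t1$fp, t1$tn), c(0L, 1L, 0L, 0L))

  expect_error(build_2x2(character(0), character(0)), "empty")
})

test_that("binary metrics match their reported fractions", {
  m <- binary_metrics(structure(list(tp = 20L, fn = 3L, fp = 3L, tn = 5L, n = 31L),
                                class = "eit_confusion2"))
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(87.0, 62.5, 80.6))

  # sensitivity 9/9, specificity 4/7; accuracy 13/16 rounds half-up to 81.3
  m2 <- binary_metrics(structure(list(tp = 9L, fn = 0L, fp = 3L, tn = 4L, n = 16L),
                                 class = "eit_confusion2"))
  expect_equal(c(m2$sensitivity, m2$specificity, m2$accuracy), c(100.0, 57.1, 81.3))

  m3 <- binary_metrics(build_2x2(c("CAT1", "NO_CAT"), c("irritant", "non_irritant")))
  expect_equal(c(m3$sensitivity, m3$specificity, m3$accuracy), c(100, 100, 100))

  # zero denominators are flagged, not NaN-propagated
  m4 <- binary_metrics(build_2x2(c("CAT1", "CAT2"), c("irritant", "irritant")))
  expect_true(is.na(m4$specificity))
  expect_match(m4$undefined, "specificity")
  expect_equal(m4$sensitivity, 100)
})

test_that("the 3x3 table places counts by (predicted, in vivo)", {
  t <- build_3x3(c("CAT2", "CAT1"), c("CAT1", "CAT1"))
  expect_identical(t["CAT1", "CAT2"], 1L)
  expect_identical(t["CAT1", "CAT1"], 1L)
  expect_identical(sum(t), 2L)

  # identity assignment puts all mass on the diagonal
  labels <- rep(c("CAT1", "CAT2", "NO_CAT"), times = c(2, 5, 3))
  ti <- build_3x3(labels, labels)
  expect_equal(unname(diag(ti)), unname(colSums(ti)))
  expect_error(build_3x3(character(0), character(0)), "empty")
})

test_that("predictivity and balanced accuracy summarize the 3x3 table", {
  t <- build_3x3(rep(c("CAT1", "CAT2", "NO_CAT"), times = c(2, 2, 2)),
                 c("CAT1", "CAT1", "CAT2", "CAT2", "NO_CAT", "NO_CAT"))
  p <- predictivity_and_balance(t)
  expect_equal(unname(p$predictivity), c(100, 100, 100))
  expect_equal(p$balanced_accuracy, 100)

  # zero column flagged as undefined
  t2 <- build_3x3(c("CAT1", "CAT2"), c("CAT1", "CAT2"))
  p2 <- predictivity_and_balance(t2)
  expect_true(is.na(p2$predictivity[["NO_CAT"]]))
  expect_match(p2$undefined, "NO_CAT")
})

test_that("metrics agree with a brute-force enumeration oracle on small label sets", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(1:10, 1)
    in_vivo <- sample(c("CAT1", "CAT2", "NO_CAT"), n, replace = TRUE)
    pred_cat <- sample(c("CAT1", "CAT2", "NO_CAT"), n, replace = TRUE)
    pred_bin <- sample(c("irritant", "non_irritant"), n, replace = TRUE)

    want <- oracle_binary(in_vivo, pred_bin)
    t <- build_2x2(in_vivo, pred_bin)
    expect_identical(c(t$tp, t$fn, t$fp, t$tn),
                     c(want$tp, want$fn, want$fp, want$tn))
    m <- binary_metrics(t)
    expect_equal(m$fractions$sensitivity, want$sensitivity)
    expect_equal(m$fractions$specificity, want$specificity)
    expect_equal(m$fractions$accuracy, want$accuracy)

    want3 <- oracle_multiclass(in_vivo, pred_cat)
    t3 <- build_3x3(in_vivo, pred_cat)
    expect_identical(unname(unclass(t3), force = TRUE),
                     unname(want3$counts, force = TRUE))
    p <- predictivity_and_balance(t3)
    expect_equal(unname(p$fractions$predictivity), unname(want3$predictivity))
    expect_equal(p$fractions$balanced_accuracy, want3$balanced)
  }
})

test_that("metrics are invariant under permutation of input pairs", {
  set.seed(42)
  in_vivo <- sample(c("CAT1", "CAT2A", "CAT2B", "NO_CAT"), 25, replace = TRUE)
  pred <- sample(c("irritant", "non_irritant"), 25, replace = TRUE)
  perm <- sample(25)
  a <- binary_metrics(build_2x2(in_vivo, pred))
  b <- binary_metrics(build_2x2(in_vivo[perm], pred[perm]))
  expect_equal(a$fractions, b$fractions)
})

test_that("the 2x2 table is the category-merged margin of a 3x3 day-1 table", {
  set.seed(43)
  in_vivo <- sample(c("CAT1", "CAT2", "NO_CAT"), 40, replace = TRUE)
  v1 <- runif(40, 0, 100)
  pred_bin <- pip1_predict(v1)
  # day-1 analogue of the 3x3: irritants provisionally CAT1, clean NO_CAT
  pred3 <- ifelse(pred_bin == "irritant", "CAT1", "NO_CAT")
  t2 <- build_2x2(in_vivo, pred_bin)
  t3 <- build_3x3(in_vivo, pred3)
  expect_identical(t2$tp, sum(t3["CAT1", c("CAT1", "CAT2")]))
  expect_identical(t2$fn, sum(t3["NO_CAT", c("CAT1", "CAT2")]))
  expect_identical(t2$fp, t3["CAT1", "NO_CAT"])
  expect_identical(t2$tn, t3["NO_CAT", "NO_CAT"])
})

test_that("uniform random guessing on balanced labels gives ~33% predictivity", {
  set.seed(44)
  n <- 10000L
  cats <- c("CAT1", "CAT2", "NO_CAT")
  in_vivo <- rep(cats, length.out = n)
  guess <- sample(cats, n, replace = TRUE)
  p <- predictivity_and_balance(build_3x3(in_vivo, guess))
  expect_equal(unname(p$fractions$predictivity), rep(1 / 3, 3), tolerance = 0.06)
  expect_equal(p$fractions$balanced_accuracy, 1 / 3, tolerance = 0.04)
})

test_that("criteria checks compare exact fractions to the regulatory thresholds", {
  panel <- load_liquid_panel()
  binary <- binary_metrics(build_2x2(panel$in_vivo_broad, panel$pip1_prediction))
  ps <- check_criteria(binary, "TG492_PS")
  got <- setNames(ps$criteria$pass, ps$criteria$criterion)
  expect_false(got[["sensitivity"]])
  expect_true(got[["specificity"]])
  expect_true(got[["accuracy"]])
  expect_false(ps$overall)

  pred <- predictivity_and_balance(build_3x3(panel$in_vivo_broad,
                                             panel$predicted_category))
  b <- check_criteria(pred, "TG492B")
  gotb <- setNames(b$criteria$pass, b$criteria$criterion)
  expect_true(gotb[["CAT1"]])
  expect_true(gotb[["CAT2"]])
  expect_false(gotb[["NO_CAT"]])

  perfect <- binary_metrics(build_2x2(rep(c("CAT1", "NO_CAT"), 5),
                                      rep(c("irritant", "non_irritant"), 5)))
  expect_true(check_criteria(perfect, "TG492_PS")$overall)
  expect_error(check_criteria(binary, "TG492C"))

  # boundary: specificity exactly 60% passes (>=), just below fails
  at60 <- binary_metrics(structure(list(tp = 9L, fn = 1L, fp = 2L, tn = 3L, n = 15L),
                                   class = "eit_confusion2"))
  expect_true(setNames(check_criteria(at60, "TG492_PS")$criteria$pass,
                       check_criteria(at60, "TG492_PS")$criteria$criterion)[["specificity"]])
})
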