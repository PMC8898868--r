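test_that("confusion counts match direct enumeration", {
  cm <- confusionCounts(c("malignant", "malignant", "benign", "benign"),
                        c("malignant", "malignant", "benign", "benign"))
  expect_identical(c(cm@tp, cm@tn, cm@fp, cm@fn), c(2L, 2L, 0L, 0L))
  cm2 <- confusionCounts(c("malignant", "benign"),
                         c("malignant", "malignant"))
  expect_identical(c(cm2@tp, cm2@fp, cm2@tn, cm2@fn), c(1L, 1L, 0L, 0L))
  for (s in 1:50) {
    set.seed(s)
    truth <- sample(c("benign", "malignant"), 100, replace = TRUE)
    pred <- sample(c("benign", "malignant"), 100, replace = TRUE)
    cm <- confusionCounts(truth, pred)
    want <- bruteConfusion(truth, pred)
    expect_identical(c(tp = cm@tp, fp = cm@fp, tn = cm@tn, fn = cm@fn), want)
  }
  expect_error(confusionCounts("benign", c("benign", "benign")), "length")
  expect_error(confusionCounts("benign", "positive"), "malignant")
})

test_that("derived metrics follow their defining ratios", {
  m <- classificationMetrics(new("ConfusionMatrix", tp = 9L, fn = 1L,
                                 tn = 0L, fp = 1L))
  expect_equal(unname(m["sensitivity"]), 0.9)
  perfect <- classificationMetrics(new("ConfusionMatrix", tp = 10L, tn = 10L,
                                       fp = 0L, fn = 0L))
  expect_equal(unname(perfect[c("sensitivity", "specificity", "accuracy",
                                "ppv")]), rep(1, 4))
  m2 <- classificationMetrics(new("ConfusionMatrix", tp = 45L, fn = 5L,
                                  tn = 40L, fp = 10L))
  expect_equal(unname(m2), c(45 / 50, 40 / 50, 85 / 100, 45 / 55))
  ## zero denominators surface as NA, never as 0
  und <- classificationMetrics(new("ConfusionMatrix", tp = 0L, fn = 0L,
                                   tn = 5L, fp = 0L))
  expect_true(is.na(und["sensitivity"]))
  expect_true(is.na(und["ppv"]))
  expect_equal(unname(und["specificity"]), 1)
})

test_that("accuracy decomposes over the class-conditional rates", {
  for (s in 1:25) {
    set.seed(s)
    v <- as.integer(rmultinom(1, 60, rep(0.25, 4)))
    if (v[1] + v[4] == 0 || v[2] + v[3] == 0) next
    cm <- new("ConfusionMatrix", tp = v[1], fp = v[2], tn = v[3], fn = v[4])
    m <- classificationMetrics(cm)
    P <- v[1] + v[4]; N <- v[2] + v[3]
    if (P == 0 || N == 0) next
    expect_equal(unname(m["accuracy"]),
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("exact binomial intervals hit their boundary cases and oracle", {
  expect_equal(unname(accuracyCI(10, 10)["upper"]), 1)
  expect_equal(unname(accuracyCI(0, 10)["lower"]), 0)
  ci <- accuracyCI(8, 10, 0.95)
  want <- stats::binom.test(8, 10, conf.level = 0.95)$conf.int
  expect_equal(unname(ci), as.numeric(want), tolerance = 1e-12)
  ## nesting: wider level contains the narrower interval
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:50, 1); k <- sample(0:n, 1)
    c95 <- accuracyCI(k, n, 0.95); c99 <- accuracyCI(k, n, 0.99)
    expect_lte(c99["lower"], c95["lower"])
    expect_gte(c99["upper"], c95["upper"])
  }
  expect_error(accuracyCI(1, 0), "trials")
  expect_error(accuracyCI(5, 3), "successes")
})

test_that("ROC curves sweep monotonically and AUC equals the U statistic", {
  r <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(aucValue(r), 1)
  ## null scores concentrate near 1/2
  set.seed(5)
  sc <- rnorm(2000); lab <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  expect_true(aucValue(rocCurve(sc, lab)) > 0.45 &&
                aucValue(rocCurve(sc, lab)) < 0.55)
  ## tie-corrected U-statistic oracle, discrete scores force ties
  for (s in 1:30) {
    set.seed(s)
    n <- sample(10:60, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(lab) || !any(lab)) next
    r <- rocCurve(sc, lab)
    expect_equal(aucValue(r), bruteAUC(sc, lab), tolerance = 1e-12)
    expect_true(!is.unsorted(r@tpr) && !is.unsorted(r@fpr))
    ## invariance under a strictly monotone transform of the scores
    expect_equal(aucValue(rocCurve(exp(3 * sc), lab)), aucValue(r),
                 tolerance = 1e-12)
  }
  expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "single class")
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- round(rnorm(300), 1)
  lab <- runif(300) < plogis(sc)
  if (all(lab) || !any(lab)) lab[1:2] <- c(TRUE, FALSE)
  want <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                         direction = "<")))
  expect_equal(aucValue(rocCurve(sc, lab)), want, tolerance = 1e-10)
})

test_that("overlap scores follow their set formulas", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(unname(overlapMetrics(a, a)), c(1, 1))
  b <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2)
  expect_equal(unname(overlapMetrics(a, b)), c(0, 0))
  ## |a| = |b| = 100 with overlap 50
  x <- matrix(FALSE, 20, 20); y <- matrix(FALSE, 20, 20)
  x[1:100] <- TRUE; y[51:150] <- TRUE
  expect_equal(unname(overlapMetrics(x, y)), c(0.5, 1 / 3))
  expect_equal(unname(overlapMetrics(matrix(FALSE, 3, 3),
                                     matrix(FALSE, 3, 3))), c(1, 1))
  expect_error(overlapMetrics(a, matrix(TRUE, 3, 3)), "shapes")
  ## dice >= jaccard, equality only at 0 or 1
  for (s in 1:25) {
    set.seed(s)
    u <- matrix(runif(64) > 0.5, 8); v <- matrix(runif(64) > 0.5, 8)
    ov <- overlapMetrics(u, v)
    expect_gte(ov["dice"], ov["jaccard"])
    if (abs(ov["dice"] - ov["jaccard"]) < 1e-15)
      expect_true(ov["dice"] %in% c(0, 1))
  }
})
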