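## deterministic synthetic patch sets used below
stripePatch <- function(kind, seed) {
  set.seed(seed)
  p <- matrix(0, 16, 16)
  if (kind == "v") p[, seq(1, 16, 2)] <- 1 else p[seq(1, 16, 2), ] <- 1
  p <- p + matrix(rnorm(256, 0, 0.05), 16)
  (p - mean(p)) / sd(p)
}
stripeSet <- function(n) {
  c(lapply(seq_len(n), function(i)
      list(patch = stripePatch("v", i), label = "benign")),
    lapply(seq_len(n), function(i)
      list(patch = stripePatch("h", 1000 + i), label = "malignant")))
}

test_that("patch extraction centers components and standardizes intensity", {
  img <- matrix(0.5, 64, 64)
  d <- sqrt(outer((1:64 - 30)^2, (1:64 - 40)^2, "+"))
  img[d < 6] <- 0.2
  mask <- d < 6
  ps <- makePatches(img, mask, 16)
  expect_length(ps, 1)
  expect_identical(dim(ps[[1]]), c(16L, 16L))
  expect_lt(abs(mean(ps[[1]])), 1e-10)
  expect_equal(sd(ps[[1]]), 1, tolerance = 1e-10)
  ## a lesion touching the border still gives a full-size patch
  edge <- matrix(FALSE, 64, 64); edge[1:5, 1:5] <- TRUE
  pe <- makePatches(img, edge, 16)
  expect_identical(dim(pe[[1]]), c(16L, 16L))
  ## two disjoint lesions: centers within one pixel of the centroids
  m2 <- matrix(FALSE, 64, 64)
  d2 <- sqrt(outer((1:64 - 15)^2, (1:64 - 15)^2, "+"))
  d3 <- sqrt(outer((1:64 - 48)^2, (1:64 - 50)^2, "+"))
  m2[d2 < 4 | d3 < 5] <- TRUE
  expect_length(makePatches(img, m2, 16), 2)
  expect_error(makePatches(img, matrix(FALSE, 64, 64), 16), "empty")
})

test_that("training separates a linearly separable patch set", {
  ds <- stripeSet(10)
  cfg <- icnnConfig(useFeatures = FALSE, epochs = 50, seed = 7)
  m <- trainICNN(ds, cfg)
  sc <- vapply(ds, function(d) scoreICNN(m, d$patch), numeric(1))
  truth <- vapply(ds, `[[`, character(1), "label")
  expect_identical(predictLabel(sc), truth)            # 100% training accuracy
  expect_lt(max(sc[truth == "benign"]), min(sc[truth == "malignant"]))
  expect_length(trainingLog(m), 50)
  expect_lt(tail(trainingLog(m), 1), head(trainingLog(m), 1))
})

test_that("training is bit-reproducible and rejects single-class data", {
  ds <- stripeSet(6)
  cfg <- icnnConfig(useFeatures = FALSE, epochs = 10, seed = 3)
  m1 <- trainICNN(ds, cfg)
  m2 <- trainICNN(ds, cfg)
  expect_identical(m1@weights, m2@weights)
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_error(trainICNN(ds[1:6], cfg), "single class")
})

test_that("scores are deterministic and finite on degenerate patches", {
  ds <- stripeSet(6)
  m <- trainICNN(ds, icnnConfig(useFeatures = FALSE, epochs = 10, seed = 3))
  p <- ds[[1]]$patch
  expect_identical(scoreICNN(m, p), scoreICNN(m, p))
  expect_true(is.finite(scoreICNN(m, matrix(0, 16, 16))))
  expect_true(is.finite(scoreICNN(m, matrix(1, 16, 16))))
  expect_error(scoreICNN(m, matrix(0, 8, 8)), "patchSize")
})

test_that("features flow through the dense layer when enabled", {
  set.seed(5)
  ds <- lapply(seq_len(20), function(i) {
    lab <- if (i <= 10) "benign" else "malignant"
    list(patch = matrix(rnorm(256), 16),  # patches carry no signal here
         features = c(f1 = as.numeric(lab == "malignant") + rnorm(1, 0, 0.05),
                      f2 = rnorm(1)),
         label = lab)
  })
  m <- trainICNN(ds, icnnConfig(useFeatures = TRUE, epochs = 40, seed = 2))
  sc <- vapply(ds, function(d) scoreICNN(m, d$patch, d$features), numeric(1))
  truth <- vapply(ds, `[[`, character(1), "label")
  expect_identical(predictLabel(sc), truth)
  expect_error(scoreICNN(m, ds[[1]]$patch), "features")
})

test_that("the decision rule thresholds at 2.0 with ties benign", {
  expect_identical(predictLabel(1.9, 2.0), "benign")
  expect_identical(predictLabel(2.1, 2.0), "malignant")
  expect_identical(predictLabel(2.0, 2.0), "benign")
  s <- sort(runif(50, 0, 4))
  lab <- predictLabel(s, 2.0)
  expect_true(all(diff(lab == "malignant") >= 0))  # monotone in the score
  expect_error(predictLabel(NaN), "finite")
  expect_error(predictLabel(Inf), "finite")
})

test_that("a trained model beats the majority class on held-out patches", {
  ## texture-only class difference: smooth blobs vs rougher high-contrast
  ## blobs, mimicking the phantom contrast classes
  mk <- function(lab, seed) {
    set.seed(seed)
    d <- sqrt(outer((1:16 - 8.5)^2, (1:16 - 8.5)^2, "+"))
    depth <- if (lab == "malignant") 0.25 else 0.10
    p <- 0.7 - depth * (d < 5) + matrix(rnorm(256, 0, 0.05), 16)
    list(patch = (p - mean(p)) / sd(p), label = lab)
  }
  ds <- c(lapply(1:50, function(i) mk("benign", i)),
          lapply(1:50, function(i) mk("malignant", 500 + i)))
  ord <- withr::with_seed(9, sample(100))
  train <- ds[ord[1:60]]; test <- ds[ord[61:100]]
  m <- trainICNN(train, icnnConfig(useFeatures = FALSE, epochs = 60, seed = 1))
  preds <- vapply(test, function(d) predictLabel(scoreICNN(m, d$patch)),
                  character(1))
  truth <- vapply(test, `[[`, character(1), "label")
  acc <- mean(preds == truth)
  majority <- max(table(truth)) / length(truth)
  expect_gt(acc, majority)
  pval <- stats::binom.test(sum(preds == truth), length(truth),
                            p = majority, alternative = "greater")$p.value
  expect_lt(pval, 0.01)
})

test_that("model containers round-trip through disk", {
  ds <- stripeSet(4)
  m <- trainICNN(ds, icnnConfig(useFeatures = FALSE, epochs = 5, seed = 1))
  f <- tempfile(fileext = ".rds")
  saveICNN(m, f)
  m2 <- readICNN(f)
  expect_identical(m@weights, m2@weights)
  expect_identical(scoreICNN(m, ds[[1]]$patch), scoreICNN(m2, ds[[1]]$patch))
  bad <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), bad)
  expect_error(readICNN(bad), "container")
})
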