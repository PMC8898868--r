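test_that("the toy co-occurrence example matches exhaustive pair counting", {
  ## classic 4x4 toy image, 4 levels, offset (1, 0 deg): the (0,0) cell holds
  ## 2 ordered right-neighbor pairs before symmetrization
  img <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 2, 2, 2), c(2, 2, 3, 3)) / 3
  ## scale so floor(x * 4) recovers the integer levels exactly
  img <- img * 3 / 4 + 1e-9
  mask <- matrix(TRUE, 4, 4)
  g <- computeGLCM(img, mask, levels = 4, p = 1, angle = 0)
  want <- bruteGLCM(img, mask, 4L, 1L, 0)
  expect_equal(glcmMatrix(g), want, tolerance = 1e-15)
  ## 12 ordered horizontal pairs in a 4x4 grid; symmetrized total 24
  expect_equal(glcmMatrix(g)[1, 1] * 24 / 2, 2)
})

test_that("a constant masked region concentrates all mass in one cell", {
  g <- computeGLCM(matrix(0.5, 6, 6), levels = 8)
  expect_equal(sum(glcmMatrix(g) > 0), 1)
  expect_equal(sum(glcmMatrix(g)), 1)
})

test_that("co-occurrence matrices equal the brute-force oracle on random images", {
  for (s in 1:25) {
    set.seed(s)
    img <- matrix(runif(16 * 16), 16)
    mask <- matrix(runif(16 * 16) > 0.2, 16)
    for (ang in c(0, 45, 90, 135)) {
      want <- bruteGLCM(img, mask, 8L, 1L, ang)
      if (is.null(want)) next
      g <- computeGLCM(img, mask, levels = 8, p = 1, angle = ang)
      expect_identical(glcmMatrix(g), want)
      expect_lt(abs(sum(glcmMatrix(g)) - 1), 1e-12)
      expect_identical(glcmMatrix(g), t(glcmMatrix(g)))  # symmetrized
    }
  }
  onepix <- matrix(FALSE, 8, 8); onepix[4, 4] <- TRUE
  expect_error(computeGLCM(matrix(0.5, 8, 8), onepix, angle = 0),
               "no valid pixel pairs")
})

test_that("GLCM statistics have their closed-form values on degenerate matrices", {
  L <- 8L
  onehot <- matrix(0, L, L); onehot[3, 3] <- 1
  f <- glcmFeatures(new("GLCM", levels = L, p = 1L, angle = 0,
                        matrix = onehot))
  expect_equal(unname(f[c("entropy", "energy", "contrast", "homogeneity")]),
               c(0, 1, 0, 1))
  unif <- matrix(1 / L^2, L, L)
  fu <- glcmFeatures(new("GLCM", levels = L, p = 1L, angle = 0, matrix = unif))
  expect_equal(unname(fu["entropy"]), log2(L^2))
})

test_that("GLCM statistics match a naive double-loop oracle", {
  for (s in 1:20) {
    set.seed(s)
    L <- sample(4:12, 1)
    q <- matrix(runif(L * L), L); q <- q / sum(q)
    g <- new("GLCM", levels = as.integer(L), p = 1L, angle = 0, matrix = q)
    expect_equal(glcmFeatures(g), bruteGLCMFeatures(q), tolerance = 1e-10)
  }
})

test_that("boundary profiles reflect region geometry", {
  n <- 81
  d <- sqrt(outer((1:n - 41)^2, (1:n - 41)^2, "+"))
  disc <- d <= 30
  prof <- boundaryProfile(disc, 64)
  expect_lt(max(abs(prof - 1)), 0.02)
  ## 2:1 axis-aligned ellipse
  dr <- outer((1:n - 41)^2 / 30^2, rep(1, n))
  dc <- outer(rep(1, n), (1:n - 41)^2 / 15^2)
  ell <- dr + dc <= 1
  p2 <- boundaryProfile(ell, 128)
  expect_lt(abs(max(p2) / min(p2) - 2), 0.2)
  ## 90-degree rotation circularly shifts the profile by a quarter turn
  rot <- t(ell)[, rev(seq_len(n))]
  p3 <- boundaryProfile(rot, 128)
  shifts <- vapply(0:127, function(k)
    max(abs(p3 - p2[(seq_len(128) + k - 1) %% 128 + 1])), numeric(1))
  expect_lt(min(shifts), 0.05)
  expect_true(which.min(shifts) %in% c(32 - 1, 32, 32 + 1, 96 - 1, 96, 96 + 1,
                                       1 + 32, 1 + 96))
  two <- disc; two[1:3, 1:3] <- TRUE
  expect_error(boundaryProfile(two), "components")
  expect_error(boundaryProfile(matrix(FALSE, 4, 4)), "empty")
})

test_that("warping distances agree with exhaustive path enumeration", {
  same <- dvwDistance(c(0.3, 0.8, 0.5), c(0.3, 0.8, 0.5))
  expect_equal(unname(same), c(0, 0, 0))
  got <- dvwDistance(c(0, 1), c(1, 0))
  oracle <- brutePaths(c(0, 1), c(1, 0))
  expect_equal(unname(got["dvw"]), oracle$dvw)
  for (s in 1:30) {
    set.seed(s)
    a <- runif(sample(1:6, 1)); b <- runif(sample(1:6, 1))
    got <- dvwDistance(a, b)
    oracle <- brutePaths(a, b)
    expect_equal(unname(got["dvw"]), oracle$dvw, tolerance = 1e-12)
    ## the reported per-path statistics belong to one of the optimal paths
    stats <- vapply(oracle$paths,
                    function(cc) c(mean(cc), max(cc)), numeric(2))
    ok <- any(abs(stats[1, ] - got["localDistance"]) < 1e-12 &
                abs(stats[2, ] - got["localCost"]) < 1e-12)
    expect_true(ok)
    ## symmetry of the distance itself
    expect_equal(unname(dvwDistance(b, a)["dvw"]), unname(got["dvw"]),
                 tolerance = 1e-12)
  }
  expect_error(dvwDistance(numeric(0), 1), "non-empty")
})

test_that("feature vectors are deterministic with sensible degenerate values", {
  n <- 41
  d <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, "+"))
  disc <- d <= 10
  img <- matrix(0.25, n, n)          # constant intensity inside the lesion
  fv <- extractFeatureVector(img, disc)
  expect_equal(unname(fv["entropy"]), 0)
  expect_identical(fv, extractFeatureVector(img, disc))
  ## a disc barely warps against the circle reference; an irregular blob of
  ## the same size warps far more
  th <- atan2(outer(rep(1, n), (1:n) - 21), outer((1:n) - 21, rep(1, n)))
  blob <- sqrt(outer((1:n - 21)^2, rep(1, n)) +
               outer(rep(1, n), (1:n - 21)^2)) <=
    10 * (1 + 0.3 * sin(4 * th))
  fvBlob <- extractFeatureVector(img, blob)
  expect_lt(unname(fv["dvw"]), 0.3 * unname(fvBlob["dvw"]))
  expect_error(extractFeatureVector(img, matrix(FALSE, n, n)), "empty")
})

test_that("malignant-class lesions score higher contrast and dvw than benign", {
  feats <- function(label, seeds) {
    t(vapply(seeds, function(s) {
      ph <- makePhantom(phantomSpec(nLesions = 1, label = label, seed = s))
      amf <- adaptiveMedianFilter(phantomImage(ph))
      extractFeatureVector(amf, lesionMask(ph))[c("contrast", "dvw")]
    }, numeric(2)))
  }
  fb <- feats("benign", 1:10)
  fm <- feats("malignant", 1:10)
  expect_gt(mean(fm[, "contrast"]), mean(fb[, "contrast"]))
  expect_gt(mean(fm[, "dvw"]), mean(fb[, "dvw"]))
})
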