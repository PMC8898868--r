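test_that("smoothed Heaviside has the arctan form", {
  expect_identical(smoothedHeaviside(0), 0.5)
  expect_equal(smoothedHeaviside(1, 1), 0.75)   # arctan(1) = pi/4
  expect_lt(smoothedHeaviside(-1e12), 1e-6)
  expect_gt(smoothedHeaviside(1e12), 1 - 1e-6)
  z <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(smoothedHeaviside(z, 0.7)) > 0))
  expect_error(smoothedHeaviside(0, -1), "positive")
})

test_that("region means reduce to weighted means of the image", {
  img <- matrix(0.42, 8, 8)
  rm0 <- regionMeans(img, matrix(rnorm(64), 8))
  expect_equal(c1(rm0), 0.42)
  expect_equal(c2(rm0), 0.42)
  ## sharp phi splitting a two-valued image along its step
  img2 <- cbind(matrix(0.2, 8, 4), matrix(0.8, 8, 4))
  phi <- cbind(matrix(-1e6, 8, 4), matrix(1e6, 8, 4))
  rm2 <- regionMeans(img2, phi, epsilon = 1)
  expect_lt(abs(c1(rm2) - 0.8), 1e-6)
  expect_lt(abs(c2(rm2) - 0.2), 1e-6)
  ## random fields against direct summation
  for (s in 1:20) {
    set.seed(s)
    im <- matrix(runif(100), 10)
    ph <- matrix(rnorm(100), 10)
    rm <- regionMeans(im, ph, epsilon = 0.8)
    h <- 0.5 * (1 + (2 / pi) * atan(ph / 0.8))
    expect_equal(c1(rm), sum(im * h) / sum(h), tolerance = 1e-12)
    expect_equal(c2(rm), sum(im * (1 - h)) / sum(1 - h), tolerance = 1e-12)
  }
  expect_error(regionMeans(img, matrix(-1e30, 8, 8), epsilon = 1),
               "interior")
})

test_that("the signed pressure force is normalized and sign-correct", {
  expect_true(all(spfField(matrix(0.5, 6, 6),
                           new("RegionMeans", c1 = 0.5, c2 = 0.5)) == 0))
  img <- cbind(matrix(0.2, 4, 2), matrix(0.8, 4, 2))
  s <- spfField(img, new("RegionMeans", c1 = 0.8, c2 = 0.2))
  expect_equal(unique(s[img == 0.8]), 1, tolerance = 1e-12)
  expect_equal(unique(s[img == 0.2]), -1, tolerance = 1e-12)
  for (seed in 1:15) {
    set.seed(seed)
    im <- matrix(runif(64), 8)
    rm <- regionMeans(im, matrix(rnorm(64), 8))
    sp <- spfField(im, rm)
    expect_lte(max(abs(sp)), 1)
    expect_equal(max(abs(sp)), 1)  # attained somewhere for non-constant input
    mid <- (c1(rm) + c2(rm)) / 2
    expect_true(all(sp[im > mid] > 0))
    expect_true(all(sp[im < mid] < 0))
  }
})

test_that("one compiled sweep matches the sweep composed from exported ops", {
  for (s in 1:4) {
    set.seed(s)
    img <- matrix(runif(32 * 32), 32)
    phi0 <- ifelse(matrix(runif(32 * 32), 32) > 0.5, 1, -1)
    dom <- if (s %% 2 == 0) ellipse <- {
      m <- matrix(FALSE, 32, 32); m[8:25, 6:27] <- TRUE; m
    } else NULL
    for (curv in c(FALSE, TRUE)) {
      ## compare the raw fields (binarization would turn rounding-order
      ## differences at sign boundaries into spurious +/-1 flips)
      p <- levelSetParams(alpha = 15, epsilon = 0.5, sigmaG = 1,
                          maxIters = 1L, tol = 0, curvature = curv,
                          binarize = FALSE)
      got <- evolveLevelSet(img, phi0, p, domain = dom)
      want <- hepaseg:::levelSetSweepR(img, phi0, p, domain = dom)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("a constant image exerts no force on the contour", {
  img <- matrix(0.6, 48, 48)
  phi0 <- matrix(-1, 48, 48); phi0[, 1:24] <- 1   # half-plane: smoothing-stable
  out <- evolveLevelSet(img, phi0, levelSetParams(maxIters = 50L))
  expect_identical(maskFromPhi(out), phi0 > 0)
})

test_that("masks derive from the sign of phi with ties exterior", {
  expect_true(all(maskFromPhi(matrix(1, 3, 3))))
  expect_false(any(maskFromPhi(matrix(-1, 3, 3))))
  expect_false(any(maskFromPhi(matrix(0, 3, 3))))
  ## signed distance to a centered disc: mask area within 2% of disc area
  n <- 101; r <- 30
  d <- sqrt(outer((1:n - 51)^2, (1:n - 51)^2, "+"))
  expect_lt(abs(sum(maskFromPhi(r - d)) - pi * r^2) / (pi * r^2), 0.02)
  expect_error(maskFromPhi(matrix(c(1, NA, 0, 0), 2)), "non-finite")
})

test_that("the evolution recovers a noiseless disc from a small interior seed", {
  sp <- phantomSpec(liverAxes = c(30, 30), nLesions = 0, gaussianSigma = 0,
                    impulseProb = 0, seed = 1)
  ph <- makePhantom(sp)
  d <- sqrt(outer((1:128 - 64.5)^2, (1:128 - 64.5)^2, "+"))
  phi0 <- ifelse(d < 8, 1, -1)                    # small seed inside the disc
  out <- evolveLevelSet(phantomImage(ph), phi0,
                        levelSetParams(maxIters = 200L))
  expect_gte(dice(maskFromPhi(out), liverMask(ph)), 0.98)
})

test_that("the field stays finite and bounded through long evolutions", {
  ## the selective-binary scheme (the default) keeps phi in [-1, 1], hence a
  ## discrete gradient bounded by 2, across arbitrarily many sweeps
  set.seed(11)
  img <- matrix(runif(32 * 32), 32)
  phi0 <- ifelse(matrix(runif(32 * 32), 32) > 0.5, 1, -1)
  out <- evolveLevelSet(img, phi0, levelSetParams(maxIters = 500L, tol = 0))
  expect_true(all(is.finite(out)))
  gr <- max(abs(diff(out)), abs(t(diff(t(out)))))
  expect_lte(gr, 2)
  ## a divergent configuration is reported, not returned
  expect_error(evolveLevelSet(img, phi0,
                              levelSetParams(dt = 1e308, maxIters = 5L)),
               "non-finite")
})

test_that("evolution is deterministic", {
  set.seed(2)
  img <- matrix(runif(40 * 40), 40)
  phi0 <- ifelse(matrix(runif(40 * 40), 40) > 0.5, 1, -1)
  p <- levelSetParams(maxIters = 30L)
  expect_identical(evolveLevelSet(img, phi0, p), evolveLevelSet(img, phi0, p))
})
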