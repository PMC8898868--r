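## Synthetic abdominal phantom generator.
##
## Each phantom is a piecewise-constant composition -- dark background, a
## bright quasi-elliptical liver, zero or more hypodense lesions -- corrupted
## by additive Gaussian noise and salt-and-pepper impulses, with ground-truth
## masks taken from the noiseless geometry.  Benign phantoms carry smooth,
## low-contrast lesions; malignant phantoms carry irregular (perturbed-
## boundary), high-contrast lesions, which gives the downstream texture
## features and classifier a learnable signal.

#' Construct a phantom specification
#'
#' Builds a validated [PhantomSpec-class].  When \code{lesionMean} is omitted
#' it defaults by class: benign lesions sit 0.10 below the liver mean (low
#' contrast), malignant lesions 0.25 below it (high contrast).  All geometry
#' is checked to fit inside the image.
#'
#' @param height,width image size in pixels.
#' @param liverCenter (row, col) center of the liver ellipse; defaults to the
#'   image center.
#' @param liverAxes semi-axes in pixels.
#' @param liverRotation ellipse rotation in radians.
#' @param liverMean,backgroundMean,lesionMean tissue intensities in [0, 1].
#' @param nLesions number of lesions.
#' @param lesionRadiusRange lesion radius range in pixels.
#' @param gaussianSigma additive Gaussian noise standard deviation.
#' @param impulseProb per-pixel salt-and-pepper probability.
#' @param label \code{"benign"} or \code{"malignant"}.
#' @param seed integer RNG seed; (spec, seed) fully determines the phantom.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(nLesions = 1, label = "malignant", seed = 7)
#' ph <- makePhantom(spec)
#' @export
phantomSpec <- function(height = 128L, width = 128L,
                        liverCenter = c((height + 1) / 2, (width + 1) / 2),
                        liverAxes = c(40, 28), liverRotation = 0,
                        liverMean = 0.7, backgroundMean = 0.3,
                        lesionMean = NULL,
                        nLesions = 1L, lesionRadiusRange = c(4, 10),
                        gaussianSigma = 0.05, impulseProb = 0.02,
                        label = c("benign", "malignant"), seed = 1L) {
  label <- match.arg(label)
  if (is.null(lesionMean))
    lesionMean <- liverMean - if (label == "malignant") 0.25 else 0.10
  new("PhantomSpec",
      height = as.integer(height), width = as.integer(width),
      liverCenter = as.numeric(liverCenter), liverAxes = as.numeric(liverAxes),
      liverRotation = as.numeric(liverRotation),
      liverMean = liverMean, backgroundMean = backgroundMean,
      lesionMean = lesionMean, nLesions = as.integer(nLesions),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      gaussianSigma = gaussianSigma, impulseProb = impulseProb,
      label = label, seed = as.integer(seed))
}

## pixel-set of a rotated ellipse on the grid of `spec`
ellipseMask <- function(nr, nc, center, axes, rotation) {
  dr <- outer(seq_len(nr) - center[1L], rep(1, nc))
  dc <- outer(rep(1, nr), seq_len(nc) - center[2L])
  u <- cos(rotation) * dr + sin(rotation) * dc
  v <- -sin(rotation) * dr + cos(rotation) * dc
  (u / axes[1L])^2 + (v / axes[2L])^2 <= 1
}

## one lesion mask: a disc (smooth = TRUE) or a radially perturbed blob.
## `wob` holds the perturbation harmonics drawn by the caller.
lesionBlobMask <- function(nr, nc, center, radius, smooth, wob) {
  dr <- outer(seq_len(nr) - center[1L], rep(1, nc))
  dc <- outer(rep(1, nr), seq_len(nc) - center[2L])
  d <- sqrt(dr^2 + dc^2)
  if (smooth) return(d <= radius)
  th <- atan2(dc, dr)
  rloc <- radius * (1 + wob$a1 * sin(wob$k1 * th + wob$p1) +
                        wob$a2 * sin(wob$k2 * th + wob$p2))
  d <= rloc
}

#' Generate one labeled phantom
#'
#' Composes the noiseless piecewise-constant image (background, liver,
#' lesions), records the ground-truth masks from that geometry, then adds
#' Gaussian noise followed by impulse noise and clips to [0, 1].  Lesions are
#' placed by rejection sampling fully inside the liver ellipse, mutually
#' disjoint; malignant lesions get a sinusoidally perturbed boundary.
#' Identical spec + seed gives bit-identical output.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [LabeledPhantom-class].
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  nr <- spec@height; nc <- spec@width
  liver <- ellipseMask(nr, nc, spec@liverCenter, spec@liverAxes,
                       spec@liverRotation)
  if (!any(liver)) stop("liver ellipse covers no pixels")

  lesion <- matrix(FALSE, nr, nc)
  withr::with_seed(spec@seed, {
    smooth <- spec@label == "benign"
    placed <- 0L
    rounds <- 0L
    while (placed < spec@nLesions) {
      rounds <- rounds + 1L
      if (rounds > 50L)
        stop("could not place ", spec@nLesions, " lesion(s) inside the liver ",
             "ellipse; enlarge the liver or shrink lesionRadiusRange")
      ok <- FALSE
      radius <- runif(1, spec@lesionRadiusRange[1L], spec@lesionRadiusRange[2L])
      ## quick-reject region: blob bounding circle must sit inside the ellipse
      margin <- radius * (if (smooth) 1 else 1.45) + 1
      probe <- ellipseMask(nr, nc, spec@liverCenter,
                           pmax(spec@liverAxes - margin, 0.5),
                           spec@liverRotation)
      for (try in seq_len(200L)) {
        ctr <- c(runif(1, 1, nr), runif(1, 1, nc))
        ri <- round(ctr[1L]); ci <- round(ctr[2L])
        if (ri < 1 || ri > nr || ci < 1 || ci > nc || !probe[ri, ci]) next
        wob <- list(a1 = runif(1, 0.15, 0.30), a2 = runif(1, 0.05, 0.15),
                    k1 = sample(3:5, 1), k2 = sample(6:9, 1),
                    p1 = runif(1, 0, 2 * pi), p2 = runif(1, 0, 2 * pi))
        cand <- lesionBlobMask(nr, nc, ctr, radius, smooth, wob)
        if (!any(cand)) next
        if (any(cand & !liver)) next
        ## disjoint with at least one pixel of separation, so ground-truth
        ## components never merge under 8-connected labeling
        grown <- EBImage::dilate(cand, EBImage::makeBrush(3L, "box")) > 0
        if (any(grown & lesion)) next
        lesion <- lesion | cand
        ok <- TRUE
        break
      }
      if (!ok) next  # redraw the radius and try again (bounded by `rounds`)
      placed <- placed + 1L
    }

    img <- matrix(spec@backgroundMean, nr, nc)
    img[liver] <- spec@liverMean
    img[lesion] <- spec@lesionMean
    if (spec@gaussianSigma > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec@gaussianSigma), nr, nc)
    img
  }) -> img
  if (spec@impulseProb > 0)
    img <- addImpulseNoise(img, spec@impulseProb, deriveSeed(spec@seed, 1L))
  img <- pmin(pmax(img, 0), 1)

  new("LabeledPhantom", image = img, liverMask = liver, lesionMask = lesion,
      label = spec@label, spec = spec)
}

#' Corrupt an image with salt-and-pepper impulse noise
#'
#' Each pixel is independently replaced, with probability \code{p}, by 0 or 1
#' with equal odds; all other pixels are untouched.
#'
#' @param image numeric matrix.
#' @param p corruption probability in [0, 1].
#' @param seed integer RNG seed.
#' @return the corrupted matrix.
#' @export
addImpulseNoise <- function(image, p, seed = 1L) {
  checkImage(image)
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]")
  withr::with_seed(as.integer(seed), {
    hit <- matrix(runif(length(image)) < p, nrow(image))
    val <- matrix(ifelse(runif(length(image)) < 0.5, 0, 1), nrow(image))
  })
  out <- image
  out[hit] <- val[hit]
  out
}

## default sampling ranges for makeDataset(); every entry is a closed
## interval (or a fixed scalar written as a degenerate interval)
defaultSpecRanges <- function() {
  list(height = c(128L, 128L), width = c(128L, 128L),
       centerJitter = c(-5, 5),
       axisA = c(34, 44), axisB = c(24, 32), rotation = c(0, pi),
       liverMean = c(0.65, 0.75), backgroundMean = c(0.25, 0.35),
       benignContrast = c(0.08, 0.12), malignantContrast = c(0.20, 0.30),
       lesionRadius = c(4, 10),
       gaussianSigma = c(0.05, 0.05), impulseProb = c(0.02, 0.02),
       benignLesionProb = 0.5, malignantMaxLesions = 2L)
}

#' Generate a labeled phantom dataset
#'
#' Draws \code{n} phantom specifications uniformly from \code{specRanges}
#' (see \code{hepaseg:::defaultSpecRanges()} for the default study
#' conditions), with exactly \code{round(n * classBalance)} malignant items in
#' a seed-determined random order.  Per-item seeds are derived from the master
#' seed by a fixed splittable scheme, so item \code{i} is reproducible
#' independently of \code{n}.  Benign phantoms carry 0 or 1 smooth
#' low-contrast lesion; malignant phantoms carry 1 or 2 irregular
#' high-contrast lesions.
#'
#' @param n number of phantoms (>= 2).
#' @param specRanges named list of parameter intervals overriding the
#'   defaults.
#' @param classBalance malignant fraction in (0, 1).
#' @param seed master integer seed.
#' @return a list of [LabeledPhantom-class] objects.
#' @export
makeDataset <- function(n, specRanges = list(), classBalance = 0.5, seed = 1L) {
  if (n < 2L) stop("n must be >= 2")
  if (classBalance <= 0 || classBalance >= 1)
    stop("classBalance must lie in (0, 1)")
  rg <- utils::modifyList(defaultSpecRanges(), specRanges)
  for (nm in setdiff(names(rg), c("benignLesionProb", "malignantMaxLesions")))
    if (length(rg[[nm]]) != 2L || diff(range(rg[[nm]])) < 0 || rg[[nm]][2L] < rg[[nm]][1L])
      stop("specRanges$", nm, " must be a non-empty interval c(lo, hi)")

  nMal <- round(n * classBalance)
  labels <- withr::with_seed(as.integer(seed),
    sample(c(rep("malignant", nMal), rep("benign", n - nMal))))

  lapply(seq_len(n), function(i) {
    sParam <- deriveSeed(seed, 2L * i)
    sItem <- deriveSeed(seed, 2L * i + 1L)
    spec <- withr::with_seed(sParam, {
      lab <- labels[i]
      h <- as.integer(rg$height[1L]); w <- as.integer(rg$width[1L])
      ctr <- c((h + 1) / 2 + runif(1, rg$centerJitter[1L], rg$centerJitter[2L]),
               (w + 1) / 2 + runif(1, rg$centerJitter[1L], rg$centerJitter[2L]))
      lm <- runif(1, rg$liverMean[1L], rg$liverMean[2L])
      contrast <- if (lab == "malignant")
        runif(1, rg$malignantContrast[1L], rg$malignantContrast[2L])
      else runif(1, rg$benignContrast[1L], rg$benignContrast[2L])
      nles <- if (lab == "malignant") sample(seq_len(rg$malignantMaxLesions), 1L)
      else stats::rbinom(1L, 1L, rg$benignLesionProb)
      phantomSpec(height = h, width = w, liverCenter = ctr,
                  liverAxes = c(runif(1, rg$axisA[1L], rg$axisA[2L]),
                                runif(1, rg$axisB[1L], rg$axisB[2L])),
                  liverRotation = runif(1, rg$rotation[1L], rg$rotation[2L]),
                  liverMean = lm,
                  backgroundMean = runif(1, rg$backgroundMean[1L], rg$backgroundMean[2L]),
                  lesionMean = lm - contrast,
                  nLesions = nles,
                  lesionRadiusRange = rg$lesionRadius,
                  gaussianSigma = runif(1, rg$gaussianSigma[1L], rg$gaussianSigma[2L]),
                  impulseProb = runif(1, rg$impulseProb[1L], rg$impulseProb[2L]),
                  label = lab, seed = sItem)
    })
    makePhantom(spec)
  })
}
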