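## Two-stage liver segmentation and the restricted lesion stage.
##
## Stage one is a conventional coarse mask: Otsu threshold, morphological
## opening, hole filling, largest connected component.  Stage two initializes
## the SPF level set from that mask and lets the region force settle the
## boundary.  The lesion stage runs the same machinery inside the liver mask,
## seeded from robust intensity outliers (beyond 2 median absolute deviations
## of the liver median) on a lightly smoothed copy of the image.

#' Coarse liver mask by global thresholding and morphology
#'
#' Otsu threshold on the (range-normalized) image, opening with a disc brush,
#' hole filling, then the largest connected component.
#'
#' @param image numeric matrix (preprocessed slice).
#' @param brushSize opening brush diameter in pixels (odd, default 5).
#' @return a logical matrix.
#' @export
coarseLiverMask <- function(image, brushSize = 5L) {
  checkImage(image)
  rng <- range(image)
  x <- if (diff(rng) > 0) (image - rng[1L]) / diff(rng) else image * 0
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256L)
  fg <- x > thr
  if (!any(fg)) stop("empty foreground after thresholding: no liver found")
  fg <- EBImage::opening(fg, EBImage::makeBrush(as.integer(brushSize), "disc"))
  fg <- EBImage::fillHull(fg) > 0
  fg <- largestComponent(matrix(as.logical(fg), nrow(image)))
  if (!any(fg)) stop("empty foreground after morphology: no liver found")
  fg
}

#' Segment the liver: coarse mask refined by the SPF level set
#'
#' Initializes phi at +1 inside [coarseLiverMask()] and -1 outside, evolves it
#' with [evolveLevelSet()] and binarizes with [maskFromPhi()].  Interior holes
#' are filled afterwards: hypodense lesions inside the organ get carved out by
#' the region force, but they belong to the liver region the mask describes.
#'
#' @param image numeric matrix (preprocessed slice).
#' @param params a [LevelSetParams-class].
#' @return a logical liver mask.
#' @export
segmentLiver <- function(image, params = levelSetParams()) {
  coarse <- coarseLiverMask(image)
  phi0 <- ifelse(coarse, 1, -1)
  m <- maskFromPhi(evolveLevelSet(image, phi0, params))
  matrix(EBImage::fillHull(m) > 0, nrow(image))
}

#' Segment lesions inside a liver mask
#'
#' Runs the SPF level set restricted to the liver: region means exclude all
#' exterior intensities and the returned mask is always contained in
#' \code{liverMask}.  Seeds are pixels of a Gaussian-smoothed copy of the
#' image (sd \code{seedSigma}) lying beyond 2 median absolute deviations of
#' the liver median, cleaned by a 3x3 morphological opening; seed components
#' whose mean contrast against the liver median stays below 4 smoothed-image
#' MADs are discarded as noise (smoothed-noise excursions cluster just past
#' the 2-MAD seed cut; real lesions sit many MADs out).  The evolution itself runs on the unsmoothed
#' image (the smoothed copy serves detection only, so lesion boundaries are
#' not blurred).  If no seed survives, the empty mask is returned.  The sign of alpha is set automatically so the contour claims
#' pixels on the seeds' side of the intensity midpoint (hypo- or hyperdense
#' lesions alike); final components smaller than \code{minArea} pixels are
#' dropped.
#'
#' @param image numeric matrix (preprocessed slice).
#' @param liverMask logical matrix, non-empty.
#' @param params a [LevelSetParams-class] for the lesion stage.
#' @param seedSigma smoothing sd (pixels) used for seeding only.
#' @param minArea smallest lesion component kept, in pixels.
#' @param boundaryMargin width (pixels) of the liver rim excluded from the
#'   lesion search: smoothing (and any liver over-segmentation) mixes liver
#'   and background intensities there, which would otherwise masquerade as a
#'   dark outlier ring.
#' @return a logical lesion mask, subset of \code{liverMask}.
#' @export
segmentLesions <- function(image, liverMask,
                           params = levelSetParams(epsilon = 0.05,
                                                   sigmaG = 0.75,
                                                   maxIters = 200L),
                           seedSigma = 1, minArea = 9L, boundaryMargin = 3L) {
  checkImage(image)
  liverMask <- asLogicalMask(liverMask, "liverMask")
  if (!identical(dim(liverMask), dim(image)))
    stop("liverMask and image shapes differ")
  if (!any(liverMask)) stop("liverMask is empty")
  empty <- liverMask & FALSE

  core <- liverMask
  if (boundaryMargin > 0) {
    er <- EBImage::erode(liverMask,
                         EBImage::makeBrush(2L * as.integer(boundaryMargin) + 1L,
                                            "disc"))
    er <- matrix(as.logical(er), nrow(image))
    if (any(er)) core <- er
  }

  sm <- gaussSmooth(image, seedSigma)
  vals <- sm[core]
  med <- median(vals)
  madv <- mad(vals)
  seeds <- if (madv > 0) core & (abs(sm - med) > 2 * madv)
           else core & (sm != med)
  if (!any(seeds)) return(empty)
  seeds <- EBImage::opening(seeds, EBImage::makeBrush(3L, "box")) > 0
  seeds <- matrix(as.logical(seeds), nrow(image)) & core
  if (!any(seeds)) return(empty)

  ## per-component contrast gate against smoothed-image noise
  lab <- EBImage::bwlabel(seeds)
  keep <- logical(max(lab))
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    keep[k] <- madv == 0 || abs(mean(sm[comp]) - med) > 4 * madv
  }
  seeds <- matrix(lab %in% which(keep) & lab > 0, nrow(image))
  if (!any(seeds)) return(empty)

  c1i <- mean(sm[seeds])
  c2i <- mean(sm[core & !seeds])
  aSign <- sign(c1i - c2i)
  if (aSign == 0) aSign <- 1
  p <- params
  p@alpha <- abs(params@alpha) * aSign

  phi0 <- ifelse(seeds, 1, -1)
  phi <- evolveLevelSet(image, phi0, p, domain = core)
  mask <- maskFromPhi(phi) & core
  dropSmallComponents(mask, minArea)
}
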