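#' @import methods
#' @importFrom stats median mad qbeta runif rnorm sd
NULL

## ---- phantom ----------------------------------------------------------------

#' Geometric and statistical description of a synthetic abdominal phantom
#'
#' A \code{PhantomSpec} fixes everything that determines one phantom slice:
#' the image grid, the liver ellipse (center, semi-axes, rotation), the
#' piecewise-constant tissue means on \code{[0, 1]}, the lesion count and size
#' range, the noise model (Gaussian sigma plus salt-and-pepper probability),
#' the class label and the RNG seed.  A spec plus its seed determines every
#' output array bit-for-bit.
#'
#' @slot height,width image size in pixels.
#' @slot liverCenter numeric length-2, (row, col) of the liver ellipse center.
#' @slot liverAxes numeric length-2, semi-axes in pixels (row-dir, col-dir
#'   before rotation).
#' @slot liverRotation rotation of the ellipse in radians.
#' @slot liverMean,backgroundMean,lesionMean tissue intensities in \code{[0,1]}.
#' @slot nLesions number of lesions (>= 0).
#' @slot lesionRadiusRange numeric length-2, lesion radius range in pixels.
#' @slot gaussianSigma standard deviation of additive Gaussian noise.
#' @slot impulseProb per-pixel salt-and-pepper corruption probability.
#' @slot label \code{"benign"} or \code{"malignant"}.  Malignant phantoms carry
#'   irregular (perturbed-boundary) high-contrast lesions, benign ones smooth
#'   low-contrast lesions.
#' @slot seed integer RNG seed.
#' @seealso [phantomSpec()], [makePhantom()]
#' @export
setClass("PhantomSpec", representation(
  height = "integer", width = "integer",
  liverCenter = "numeric", liverAxes = "numeric", liverRotation = "numeric",
  liverMean = "numeric", backgroundMean = "numeric", lesionMean = "numeric",
  nLesions = "integer", lesionRadiusRange = "numeric",
  gaussianSigma = "numeric", impulseProb = "numeric",
  label = "character", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  mns <- c(object@liverMean, object@backgroundMean, object@lesionMean)
  if (any(mns < 0 | mns > 1)) msg <- c(msg, "tissue means must lie in [0, 1]")
  if (object@height < 8L || object@width < 8L)
    msg <- c(msg, "image must be at least 8x8")
  if (!object@label %in% c("benign", "malignant"))
    msg <- c(msg, "label must be 'benign' or 'malignant'")
  if (object@nLesions < 0L) msg <- c(msg, "nLesions must be >= 0")
  if (object@impulseProb < 0 || object@impulseProb > 1)
    msg <- c(msg, "impulseProb must lie in [0, 1]")
  if (object@gaussianSigma < 0) msg <- c(msg, "gaussianSigma must be >= 0")
  if (any(object@lesionRadiusRange <= 0) ||
      diff(object@lesionRadiusRange) < 0)
    msg <- c(msg, "lesionRadiusRange must be positive and non-decreasing")
  ## bounding box of the rotated ellipse must fit strictly inside the grid
  a <- object@liverAxes[1L]; b <- object@liverAxes[2L]
  th <- object@liverRotation
  hr <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  hc <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  ctr <- object@liverCenter
  if (ctr[1L] - hr < 1 || ctr[1L] + hr > object@height ||
      ctr[2L] - hc < 1 || ctr[2L] + hc > object@width)
    msg <- c(msg, "liver ellipse does not fit inside the image bounds")
  if (length(msg)) msg else TRUE
})

#' A generated phantom with ground truth
#'
#' Holds the noisy image, the noiseless ground-truth liver and lesion masks,
#' the class label and the generating [PhantomSpec-class].  The lesion mask is
#' always a subset of the liver mask.
#'
#' @slot image numeric matrix in \code{[0, 1]}.
#' @slot liverMask,lesionMask logical matrices, same shape as \code{image}.
#' @slot label \code{"benign"} or \code{"malignant"}.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("LabeledPhantom", representation(
  image = "matrix", liverMask = "matrix", lesionMask = "matrix",
  label = "character", spec = "PhantomSpec"
))

setValidity("LabeledPhantom", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@liverMask)) ||
      !identical(dim(object@image), dim(object@lesionMask)))
    msg <- c(msg, "image and masks must share one shape")
  if (any(object@lesionMask & !object@liverMask))
    msg <- c(msg, "lesion mask must be contained in the liver mask")
  if (length(msg)) msg else TRUE
})

## ---- preprocessing ----------------------------------------------------------

#' Normalized gray-level histogram
#'
#' Relative frequency of each of \code{levels} gray levels; entries are
#' non-negative and sum to one.
#'
#' @slot levels integer, number of gray levels L.
#' @slot q numeric vector of L relative frequencies.
#' @seealso [normalizedHistogram()]
#' @export
setClass("Histogram", representation(levels = "integer", q = "numeric"))

setValidity("Histogram", function(object) {
  msg <- character()
  if (object@levels < 2L) msg <- c(msg, "levels must be >= 2")
  if (length(object@q) != object@levels)
    msg <- c(msg, "q must have one entry per level")
  if (any(object@q < 0)) msg <- c(msg, "frequencies must be >= 0")
  if (abs(sum(object@q) - 1) > 1e-12)
    msg <- c(msg, "frequencies must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Monotone gray-level remapping derived from a cumulative histogram
#'
#' \code{mapping[k]} is the output level assigned to input level \code{k - 1};
#' the mapping is monotone non-decreasing with values in \code{[0, L-1]}.
#'
#' @slot levels integer, number of gray levels L.
#' @slot mapping integer vector of L output levels.
#' @seealso [equalizationMap()]
#' @export
setClass("EqualizationMap", representation(levels = "integer",
                                           mapping = "integer"))

setValidity("EqualizationMap", function(object) {
  msg <- character()
  if (length(object@mapping) != object@levels)
    msg <- c(msg, "mapping must have one entry per level")
  if (any(diff(object@mapping) < 0L))
    msg <- c(msg, "mapping must be monotone non-decreasing")
  if (any(object@mapping < 0L | object@mapping > object@levels - 1L))
    msg <- c(msg, "mapping values must lie in [0, L-1]")
  if (length(msg)) msg else TRUE
})

## ---- level set --------------------------------------------------------------

#' Mean intensities inside and outside the evolving contour
#'
#' Weighted means of the image under the smoothed Heaviside of the level-set
#' field: \code{c1} is the interior mean (weight \eqn{H_\epsilon(\phi)}),
#' \code{c2} the exterior mean (weight \eqn{1 - H_\epsilon(\phi)}).
#'
#' @slot c1,c2 numeric scalars.
#' @seealso [regionMeans()]
#' @export
setClass("RegionMeans", representation(c1 = "numeric", c2 = "numeric"))

#' Parameters of the signed-pressure-force level-set evolution
#'
#' @slot alpha balloon-force weight (dimensionless, non-zero; its sign selects
#'   whether the contour claims pixels brighter or darker than the region-mean
#'   midpoint).
#' @slot epsilon width of the arctan-smoothed Heaviside, in units of phi.
#' @slot dt evolution time step.
#' @slot sigmaG standard deviation (pixels) of the Gaussian regularization
#'   applied to phi after each sweep, in place of re-initialization.
#' @slot maxIters maximum number of sweeps.
#' @slot tol stopping tolerance: the evolution stops when the fraction of
#'   pixels whose sign changed between sweeps drops to \code{tol} or below.
#' @slot binarize logical; re-binarize phi to +/-1 after every sweep
#'   (selective-binary variant, the default).
#' @slot curvature logical; add the curvature term
#'   \eqn{spf \cdot \mathrm{div}(\nabla\phi/|\nabla\phi|)} to the update
#'   (off by default: the simplified formulation drops it).
#' @seealso [levelSetParams()], [evolveLevelSet()]
#' @export
setClass("LevelSetParams", representation(
  alpha = "numeric", epsilon = "numeric", dt = "numeric", sigmaG = "numeric",
  maxIters = "integer", tol = "numeric",
  binarize = "logical", curvature = "logical"
))

setValidity("LevelSetParams", function(object) {
  msg <- character()
  if (object@alpha == 0) msg <- c(msg, "alpha must be non-zero")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@sigmaG <= 0) msg <- c(msg, "sigmaG must be > 0")
  if (object@maxIters < 1L) msg <- c(msg, "maxIters must be >= 1")
  if (object@tol < 0) msg <- c(msg, "tol must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---- texture ----------------------------------------------------------------

#' Normalized gray-level co-occurrence matrix
#'
#' Symmetric co-occurrence frequencies of quantized gray-level pairs at one
#' pixel offset (distance \code{p} along angle \code{angle}).  Entries are
#' non-negative and sum to one.
#'
#' @slot levels integer, number of quantization levels L.
#' @slot p integer offset distance in pixels.
#' @slot angle offset angle in degrees: one of 0, 45, 90, 135.
#' @slot matrix L x L numeric matrix of normalized frequencies.
#' @seealso [computeGLCM()], [glcmFeatures()]
#' @export
setClass("GLCM", representation(levels = "integer", p = "integer",
                                angle = "numeric", matrix = "matrix"))

setValidity("GLCM", function(object) {
  msg <- character()
  if (!object@angle %in% c(0, 45, 90, 135))
    msg <- c(msg, "angle must be one of 0, 45, 90, 135")
  if (!identical(dim(object@matrix),
                 c(as.integer(object@levels), as.integer(object@levels))))
    msg <- c(msg, "matrix must be levels x levels")
  if (any(object@matrix < 0)) msg <- c(msg, "entries must be >= 0")
  if (abs(sum(object@matrix) - 1) > 1e-12)
    msg <- c(msg, "entries must sum to 1")
  if (length(msg)) msg else TRUE
})

## ---- classifier -------------------------------------------------------------

#' Configuration of the thresholded convolutional scorer
#'
#' @slot patchSize side length (pixels) of the square lesion patches (>= 8).
#' @slot convChannels integer vector, output channels of the two 3x3
#'   convolution blocks.
#' @slot denseUnits width of the hidden dense layer.
#' @slot learningRate Adam learning rate.
#' @slot epochs number of training epochs.
#' @slot batchSize mini-batch size.
#' @slot threshold scalar decision threshold: scores above it are called
#'   malignant, at or below it benign.  Default 2.0, matched by the training
#'   targets (benign 1.0, malignant 3.0).
#' @slot useFeatures logical; concatenate the texture [extractFeatureVector()]
#'   descriptors to the flattened convolutional activations before the dense
#'   layers.
#' @slot seed integer RNG seed for weight initialization and batch order.
#' @seealso [icnnConfig()], [trainICNN()]
#' @export
setClass("ICNNConfig", representation(
  patchSize = "integer", convChannels = "integer", denseUnits = "integer",
  learningRate = "numeric", epochs = "integer", batchSize = "integer",
  threshold = "numeric", useFeatures = "logical", seed = "integer"
))

setValidity("ICNNConfig", function(object) {
  msg <- character()
  if (object@patchSize < 8L) msg <- c(msg, "patchSize must be >= 8")
  if (object@patchSize %% 4L != 0L)
    msg <- c(msg, "patchSize must be divisible by 4 (two 2x2 poolings)")
  if (length(object@convChannels) != 2L || any(object@convChannels < 1L))
    msg <- c(msg, "convChannels must be two positive counts")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (!is.finite(object@threshold)) msg <- c(msg, "threshold must be finite")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' A trained convolutional scorer
#'
#' @slot config the [ICNNConfig-class] used for training.
#' @slot weights named list of weight arrays.
#' @slot featureCenter,featureScale per-feature standardization constants
#'   estimated on the training set (empty when \code{useFeatures} is off).
#' @slot trainingLog numeric vector of per-epoch mean squared losses.
#' @export
setClass("ICNNModel", representation(
  config = "ICNNConfig", weights = "list",
  featureCenter = "numeric", featureScale = "numeric",
  trainingLog = "numeric"
))

## ---- evaluation -------------------------------------------------------------

#' Binary confusion counts with malignant as the positive class
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @seealso [confusionCounts()], [classificationMetrics()]
#' @export
setClass("ConfusionMatrix", representation(
  tp = "integer", fp = "integer", tn = "integer", fn = "integer"
))

setValidity("ConfusionMatrix", function(object) {
  cnt <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(cnt < 0L)) return("counts must be non-negative")
  if (sum(cnt) < 1L) return("at least one observation is required")
  TRUE
})

#' ROC curve with trapezoid AUC
#'
#' @slot thresholds decreasing score thresholds of the sweep.
#' @slot tpr,fpr true/false positive rates along the sweep, in \code{[0, 1]}.
#' @slot auc area under the curve by the trapezoid rule (equals the
#'   tie-corrected normalized Mann-Whitney U statistic).
#' @seealso [rocCurve()]
#' @export
setClass("RocCurve", representation(
  thresholds = "numeric", tpr = "numeric", fpr = "numeric", auc = "numeric"
))

setValidity("RocCurve", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    msg <- c(msg, "tpr and fpr must be monotone along the sweep")
  if (length(msg)) msg else TRUE
})
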