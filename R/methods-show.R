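## show() methods and small accessors

#' @describeIn PhantomSpec-class compact display
#' @param object a \code{PhantomSpec}
#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %dx%d | liver %.2f bg %.2f lesion %.2f | %d lesion(s) | %s | seed %d\n",
              object@height, object@width, object@liverMean,
              object@backgroundMean, object@lesionMean, object@nLesions,
              object@label, object@seed))
  cat(sprintf("  noise: gaussian sigma %.3f, impulse p %.3f\n",
              object@gaussianSigma, object@impulseProb))
  invisible(NULL)
})

#' @describeIn LabeledPhantom-class compact display
#' @param object a \code{LabeledPhantom}
#' @export
setMethod("show", "LabeledPhantom", function(object) {
  cat(sprintf("LabeledPhantom %dx%d | label %s | liver %d px | lesion %d px\n",
              nrow(object@image), ncol(object@image), object@label,
              sum(object@liverMask), sum(object@lesionMask)))
  invisible(NULL)
})

#' @describeIn GLCM-class compact display
#' @param object a \code{GLCM}
#' @export
setMethod("show", "GLCM", function(object) {
  cat(sprintf("GLCM %dx%d | offset p=%d angle=%g deg | sum=%.6f\n",
              object@levels, object@levels, object@p, object@angle,
              sum(object@matrix)))
  invisible(NULL)
})

#' @describeIn ConfusionMatrix-class 2x2 table display
#' @param object a \code{ConfusionMatrix}
#' @export
setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(truth = c("malignant", "benign"),
                              predicted = c("malignant", "benign")))
  print(m)
  invisible(NULL)
})

#' @describeIn RocCurve-class compact display
#' @param object a \code{RocCurve}
#' @export
setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve | %d thresholds | AUC %.4f\n",
              length(object@thresholds), object@auc))
  invisible(NULL)
})

#' @describeIn ICNNModel-class compact display
#' @param object an \code{ICNNModel}
#' @export
setMethod("show", "ICNNModel", function(object) {
  cfg <- object@config
  cat(sprintf("ICNNModel | patch %d | conv %s | dense %d | %s | %d epochs, final loss %.4f\n",
              cfg@patchSize, paste(cfg@convChannels, collapse = "-"),
              cfg@denseUnits,
              if (cfg@useFeatures) "patch+features" else "patch only",
              length(object@trainingLog),
              utils::tail(object@trainingLog, 1)))
  invisible(NULL)
})

#' Interior and exterior region means
#'
#' Accessors for the two weighted means held by a [RegionMeans-class].
#' @param x a \code{RegionMeans}
#' @return a numeric scalar.
#' @export
c1 <- function(x) { stopifnot(is(x, "RegionMeans")); x@c1 }

#' @rdname c1
#' @export
c2 <- function(x) { stopifnot(is(x, "RegionMeans")); x@c2 }

#' GLCM matrix accessor
#' @param x a [GLCM-class]
#' @return the L x L numeric matrix of normalized co-occurrence frequencies.
#' @export
glcmMatrix <- function(x) { stopifnot(is(x, "GLCM")); x@matrix }

#' Phantom accessors
#'
#' @param x a [LabeledPhantom-class]
#' @return \code{phantomImage}: the noisy image matrix; \code{liverMask},
#'   \code{lesionMask}: logical ground-truth masks; \code{phantomLabel}: the
#'   class label.
#' @export
phantomImage <- function(x) { stopifnot(is(x, "LabeledPhantom")); x@image }

#' @rdname phantomImage
#' @export
liverMask <- function(x) { stopifnot(is(x, "LabeledPhantom")); x@liverMask }

#' @rdname phantomImage
#' @export
lesionMask <- function(x) { stopifnot(is(x, "LabeledPhantom")); x@lesionMask }

#' @rdname phantomImage
#' @export
phantomLabel <- function(x) { stopifnot(is(x, "LabeledPhantom")); x@label }

#' AUC accessor
#' @param x a [RocCurve-class]
#' @return the trapezoid area under the curve.
#' @export
aucValue <- function(x) { stopifnot(is(x, "RocCurve")); x@auc }

#' Training-log accessor
#' @param x an [ICNNModel-class]
#' @return numeric vector of per-epoch mean squared losses.
#' @export
trainingLog <- function(x) { stopifnot(is(x, "ICNNModel")); x@trainingLog }
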