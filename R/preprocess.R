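## Preprocessing: histogram equalization and adaptive median filtering.
##
## Equalization is the standard discrete CDF remapping: each gray level k is
## sent to round((L-1) * CDF(k)), rounding half away from zero.  The adaptive
## median filter is the canonical two-stage formulation: the window grows from
## 3x3 until its median is non-degenerate (strictly between the window min and
## max); a pixel that is itself a window extreme is replaced by that median,
## any other pixel is kept; if the largest window is reached with a still
## degenerate median the window median is output.  Borders are reflect-padded.

#' Quantize a continuous image to L gray levels
#'
#' Float images on [0, 1] are mapped to integer levels 0..L-1 by
#' \code{floor(x * (L - 1) + 0.5)}; values outside [0, 1] are clipped first.
#' Images already holding integers in 0..L-1 pass through unchanged.
#'
#' @param image numeric matrix.
#' @param levels number of gray levels L (>= 2).
#' @return an integer-valued matrix with entries in 0..L-1.
#' @export
quantizeImage <- function(image, levels = 256L) {
  checkImage(image)
  if (levels < 2L) stop("levels must be >= 2")
  if (all(image == floor(image)) && min(image) >= 0 && max(image) <= levels - 1L)
    return(image)
  x <- pmin(pmax(image, 0), 1)
  roundHalfUp(x * (levels - 1L))
}

#' Normalized gray-level histogram of an image
#'
#' \code{q[k]} is the fraction of pixels at level \code{k - 1} (levels run
#' 0..L-1).
#'
#' @param image numeric matrix, quantizable to \code{levels} gray levels.
#' @param levels number of gray levels L (>= 2).
#' @return a [Histogram-class].
#' @examples
#' h <- normalizedHistogram(matrix(c(0, 0, 1, 3), 2), levels = 4)
#' h@q  # 0.50 0.25 0.00 0.25
#' @export
normalizedHistogram <- function(image, levels = 256L) {
  if (levels < 2L) stop("levels must be >= 2")
  z <- quantizeImage(image, levels)
  counts <- tabulate(as.integer(z) + 1L, nbins = as.integer(levels))
  new("Histogram", levels = as.integer(levels), q = counts / sum(counts))
}

#' Equalization map from a histogram
#'
#' Maps input level k to \code{round((L - 1) * CDF(k))} where CDF is the
#' cumulative histogram; rounding is half away from zero.  The map is always
#' monotone non-decreasing.
#'
#' @param hist a [Histogram-class].
#' @return an [EqualizationMap-class].
#' @export
equalizationMap <- function(hist) {
  stopifnot(is(hist, "Histogram"))
  validObject(hist)
  cdf <- cumsum(hist@q)
  mapping <- as.integer(roundHalfUp((hist@levels - 1L) * cdf))
  mapping <- pmin(pmax(mapping, 0L), hist@levels - 1L)
  new("EqualizationMap", levels = hist@levels, mapping = as.integer(mapping))
}

#' Histogram-equalize an image
#'
#' Every pixel is passed through the equalization map of the image's own
#' histogram; output levels lie in 0..L-1.
#'
#' @param image numeric matrix.
#' @param levels number of gray levels L (default 256, the 8-bit convention).
#' @return a matrix of integer gray levels in 0..L-1.
#' @export
histogramEqualize <- function(image, levels = 256L) {
  z <- quantizeImage(image, levels)
  m <- equalizationMap(normalizedHistogram(z, levels))
  out <- m@mapping[as.integer(z) + 1L]
  matrix(as.numeric(out), nrow(image))
}

#' Adaptive median filter for impulse noise
#'
#' Classical two-stage adaptive median filtering with reflect-padded borders;
#' see the module header for the stage logic.  Removes salt-and-pepper
#' impulses while leaving uncorrupted pixels (including edges) untouched.
#' The output range is always contained in the input range.
#'
#' @param image numeric matrix.
#' @param maxWindow largest window side, odd and >= 3 (default 7).
#' @return the filtered matrix.
#' @examples
#' x <- matrix(0.5, 9, 9); x[5, 5] <- 1  # one impulse
#' y <- adaptiveMedianFilter(x)
#' y[5, 5]  # 0.5
#' @export
adaptiveMedianFilter <- function(image, maxWindow = 7L) {
  checkImage(image)
  maxWindow <- as.integer(maxWindow)
  if (maxWindow < 3L || maxWindow %% 2L == 0L)
    stop("maxWindow must be odd and >= 3")
  amf_cpp(image, maxWindow)
}
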