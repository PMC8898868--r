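## internal helpers shared across modules

## Derive a per-item seed from a master seed.  Fixed splittable scheme:
## seed_i = (master * 48271 + i * 10007) mod (2^31 - 1), kept below 2^31 so it
## is always a valid R integer.  Documented in the methods vignette; stable
## under dataset resizing (item i keeps its seed when n changes).
deriveSeed <- function(master, i) {
  as.integer((as.double(master %% 2147483647L) * 48271 + i * 10007) %% 2147483647)
}

## round half away from zero (inputs here are always >= 0)
roundHalfUp <- function(x) floor(x + 0.5)

## Gaussian smoothing of a plain matrix; separable kernel truncated at
## radius 3*sigma, reflected boundary (compiled)
gaussSmooth <- function(m, sigma) gauss_smooth_cpp(m, sigma)

## largest connected component of a logical matrix (8-connectivity);
## returns an all-FALSE matrix when the input is empty
largestComponent <- function(mask) {
  if (!any(mask)) return(mask & FALSE)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  matrix(lab == which.max(tab), nrow = nrow(mask))
}

## drop connected components smaller than minArea pixels
dropSmallComponents <- function(mask, minArea) {
  if (!any(mask) || minArea <= 1) return(mask)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= minArea)
  matrix(lab %in% keep & lab > 0, nrow = nrow(mask))
}

## centroid (row, col) of a logical matrix
maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1L]), mean(idx[, 2L]))
}

asLogicalMask <- function(m, what = "mask") {
  if (is.logical(m)) return(m)
  if (is.numeric(m)) return(m > 0)
  stop(what, " must be a logical or numeric matrix")
}

checkImage <- function(image, what = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(what, " must be a numeric matrix")
  if (any(!is.finite(image))) stop(what, " contains non-finite values")
  invisible(image)
}
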