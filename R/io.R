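## Image and mask I/O.  PNG/TIFF go through EBImage; single-slice NIfTI
## through RNifti.  Images are numeric matrices in [0, 1]; masks are written
## as 0/255 8-bit PNG (or 0/1 NIfTI) and read back as logical matrices.

imageFormat <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.png$", lp)) return("png")
  if (grepl("\\.tiff?$", lp)) return("tiff")
  stop("unsupported image format: ", basename(path),
       " (expected .png, .tif/.tiff or .nii/.nii.gz)")
}

#' Read a 2-D grayscale image
#'
#' PNG and TIFF are read through EBImage (multi-channel images are averaged
#' to one gray channel); NIfTI through RNifti, taking the first slice of any
#' trailing dimensions.  Returns a numeric matrix; PNG/TIFF are on [0, 1]
#' while NIfTI values are rescaled to [0, 1] by their range when
#' \code{rescale} is on.
#'
#' @param path input file.
#' @param rescale rescale NIfTI intensities to [0, 1] (default TRUE).
#' @return a numeric matrix.
#' @export
readImage2D <- function(path, rescale = TRUE) {
  fmt <- imageFormat(path)
  if (fmt == "nifti") {
    v <- RNifti::readNifti(path)
    a <- as.array(v)
    while (length(dim(a)) > 2L) a <- a[, , 1L]
    m <- matrix(as.numeric(a), nrow(a))
    if (rescale && diff(range(m)) > 0)
      m <- (m - min(m)) / diff(range(m))
    return(m)
  }
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
  ## EBImage stores (x, y); transpose to (row, col)
  t(matrix(as.numeric(a), nrow(a)))
}

#' Write a 2-D grayscale image
#'
#' @param image numeric matrix; clipped to [0, 1] for PNG/TIFF.
#' @param path output file (.png, .tif/.tiff, .nii/.nii.gz).
#' @return the path, invisibly.
#' @export
writeImage2D <- function(image, path) {
  checkImage(image)
  fmt <- imageFormat(path)
  if (fmt == "nifti") {
    RNifti::writeNifti(RNifti::asNifti(image), path)
  } else {
    x <- pmin(pmax(image, 0), 1)
    EBImage::writeImage(EBImage::Image(t(x)), path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Write a binary mask as 0/255 PNG (or 0/1 NIfTI)
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  mask <- asLogicalMask(mask)
  if (imageFormat(path) == "nifti")
    RNifti::writeNifti(RNifti::asNifti(mask * 1), path)
  else
    EBImage::writeImage(EBImage::Image(t(mask * 1)), path,
                        bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask
#'
#' Any strictly positive pixel is foreground.
#'
#' @param path input file.
#' @return a logical matrix.
#' @export
readMask <- function(path) {
  readImage2D(path, rescale = FALSE) > 0
}

#' Write a dataset manifest
#'
#' Records every phantom's generating spec (all slots, including seeds) and
#' the file names of its image and masks in one JSON sidecar, so a written
#' dataset can be regenerated bit-for-bit.
#'
#' @param phantoms list of [LabeledPhantom-class].
#' @param files data.frame or list with per-item file names (optional).
#' @param path output .json file.
#' @return the path, invisibly.
#' @export
writeManifest <- function(phantoms, path, files = NULL) {
  entries <- lapply(seq_along(phantoms), function(i) {
    sp <- phantoms[[i]]@spec
    e <- list(index = i, label = sp@label, seed = sp@seed,
              height = sp@height, width = sp@width,
              liverCenter = sp@liverCenter, liverAxes = sp@liverAxes,
              liverRotation = sp@liverRotation,
              liverMean = sp@liverMean, backgroundMean = sp@backgroundMean,
              lesionMean = sp@lesionMean, nLesions = sp@nLesions,
              lesionRadiusRange = sp@lesionRadiusRange,
              gaussianSigma = sp@gaussianSigma, impulseProb = sp@impulseProb)
    if (!is.null(files)) e$files <- as.list(files[[i]])
    e
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
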