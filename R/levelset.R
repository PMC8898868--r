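## Region-based signed-pressure-force (SPF) level set.
##
## The contour is the zero level of a signed field phi (interior phi > 0).
## Each sweep recomputes the interior/exterior means under an arctan-smoothed
## Heaviside, forms the normalized signed pressure force
##   spf(x) = (I(x) - (c1 + c2)/2) / max |I - (c1 + c2)/2|   in [-1, 1],
## and advances phi by dt * alpha * spf * |grad phi| with a first-order upwind
## discretization keyed to the sign of alpha * spf.  Instead of
## re-initialization, phi is Gaussian-smoothed after every sweep and (by
## default) re-binarized to +/-1, the selective-binary variant of the scheme.

#' Level-set evolution parameters
#'
#' @param alpha balloon-force weight (non-zero).  Positive alpha makes the
#'   contour claim pixels brighter than the midpoint of the two region means;
#'   negative alpha claims darker pixels.
#' @param epsilon smoothing width of the Heaviside (in units of phi).
#' @param dt time step.
#' @param sigmaG Gaussian regularization standard deviation in pixels.
#' @param maxIters maximum sweeps.
#' @param tol stop when the fraction of sign-changed pixels per sweep is
#'   \code{<= tol}.
#' @param binarize re-binarize phi to +/-1 each sweep (default on).
#' @param curvature include the curvature term
#'   \eqn{spf \cdot \mathrm{div}(\nabla\phi/|\nabla\phi|)} (default off; the
#'   simplified evolution drops it).
#' @return a [LevelSetParams-class].
#' @export
levelSetParams <- function(alpha = 20, epsilon = 1, dt = 1, sigmaG = 1,
                           maxIters = 500L, tol = 1e-4,
                           binarize = TRUE, curvature = FALSE) {
  new("LevelSetParams", alpha = alpha, epsilon = epsilon, dt = dt,
      sigmaG = sigmaG, maxIters = as.integer(maxIters), tol = tol,
      binarize = binarize, curvature = curvature)
}

#' Arctan-smoothed Heaviside step
#'
#' \eqn{H_\epsilon(z) = \frac12 (1 + \frac{2}{\pi} \arctan(z/\epsilon))},
#' a strictly increasing map into (0, 1) with \eqn{H_\epsilon(0) = 1/2}.
#'
#' @param z numeric (vectorized).
#' @param epsilon smoothing width, > 0.
#' @return values in (0, 1).
#' @export
smoothedHeaviside <- function(z, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar")
  0.5 * (1 + (2 / pi) * atan(z / epsilon))
}

#' Interior and exterior region means
#'
#' Weighted means of the image under \eqn{H_\epsilon(\phi)} (interior) and
#' \eqn{1 - H_\epsilon(\phi)} (exterior).  With a \code{domain} mask, only
#' pixels inside the domain contribute (the restricted lesion stage).
#'
#' @param image numeric matrix.
#' @param phi level-set field, same shape.
#' @param epsilon Heaviside smoothing width.
#' @param domain optional logical matrix restricting the computation.
#' @return a [RegionMeans-class].
#' @export
regionMeans <- function(image, phi, epsilon = 1, domain = NULL) {
  checkImage(image)
  if (!identical(dim(image), dim(phi))) stop("image and phi shapes differ")
  h <- smoothedHeaviside(phi, epsilon)
  w <- if (is.null(domain)) matrix(1, nrow(image), ncol(image))
       else asLogicalMask(domain) * 1
  w1 <- sum(h * w); w2 <- sum((1 - h) * w)
  if (w1 < 1e-12) stop("degenerate interior region (zero weight)")
  if (w2 < 1e-12) stop("degenerate exterior region (zero weight)")
  new("RegionMeans", c1 = sum(image * h * w) / w1,
      c2 = sum(image * (1 - h) * w) / w2)
}

#' Normalized signed pressure force
#'
#' \eqn{spf(x) = (I(x) - (c_1+c_2)/2) / \max_x |I(x) - (c_1+c_2)/2|}; the
#' all-zero field when the maximum deviation vanishes (below 1e-12, i.e. a
#' constant image up to rounding noise).  Values always lie in \eqn{[-1, 1]}, positive where the image
#' exceeds the midpoint of the two region means.
#'
#' @param image numeric matrix.
#' @param means a [RegionMeans-class].
#' @return a matrix in \eqn{[-1, 1]}.
#' @export
spfField <- function(image, means) {
  checkImage(image)
  stopifnot(is(means, "RegionMeans"))
  dev <- image - (means@c1 + means@c2) / 2
  m <- max(abs(dev))
  if (m <= 1e-12) return(dev * 0)  # constant image up to rounding noise
  dev / m
}

## shift a matrix by one pixel with replicate (Neumann) boundary
shiftRow <- function(m, d) {
  nr <- nrow(m)
  if (d == 1L) m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  else m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
}
shiftCol <- function(m, d) {
  nc <- ncol(m)
  if (d == 1L) m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  else m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
}

## curvature div(grad phi / |grad phi|) by central differences
curvatureOf <- function(phi) {
  eps <- 1e-8
  pr <- (shiftRow(phi, -1L) - shiftRow(phi, 1L)) / 2
  pc <- (shiftCol(phi, -1L) - shiftCol(phi, 1L)) / 2
  g <- sqrt(pr^2 + pc^2) + eps
  nr <- pr / g; ncl <- pc / g
  (shiftRow(nr, -1L) - shiftRow(nr, 1L)) / 2 +
    (shiftCol(ncl, -1L) - shiftCol(ncl, 1L)) / 2
}

#' Evolve a level-set field under the signed pressure force
#'
#' Iterates the sweep described in the module header until the fraction of
#' sign-changed pixels drops to \code{tol} or \code{maxIters} is reached.
#' With a \code{domain} mask (the lesion stage), region means and the force
#' are restricted to the domain and phi is clamped negative outside it, so
#' the recovered region can never escape the domain.
#'
#' @param image numeric matrix.
#' @param phi0 initial field, same shape (interior positive).
#' @param params a [LevelSetParams-class].
#' @param domain optional logical matrix restricting the evolution.
#' @return the final field (a matrix).
#' @seealso [maskFromPhi()], [segmentLiver()], [segmentLesions()]
#' @export
evolveLevelSet <- function(image, phi0, params = levelSetParams(),
                           domain = NULL) {
  checkImage(image)
  validObject(params)
  if (!identical(dim(image), dim(phi0))) stop("image and phi0 shapes differ")
  if (!is.null(domain)) {
    domain <- asLogicalMask(domain, "domain")
    if (!identical(dim(domain), dim(image)))
      stop("domain and image shapes differ")
  }
  evolve_cpp(image, phi0, params@alpha, params@epsilon, params@dt,
             params@sigmaG, params@maxIters, params@tol, params@binarize,
             params@curvature, domain)
}

## one evolution sweep composed from the exported building blocks; the
## reference the compiled loop is tested against
levelSetSweepR <- function(image, phi, params, domain = NULL) {
  if (!is.null(domain)) phi[!domain] <- -1   # exterior is clamped throughout
  rm <- regionMeans(image, phi, params@epsilon, domain)
  spf <- spfField(image, rm)
  if (!is.null(domain)) {
    spf[!domain] <- 0
    m <- max(abs(spf))
    if (m > 1e-12) spf <- spf / m else spf <- spf * 0
  }
  FF <- params@alpha * spf
  dpr <- shiftRow(phi, -1L) - phi   # forward row difference
  dmr <- phi - shiftRow(phi, 1L)    # backward row difference
  dpc <- shiftCol(phi, -1L) - phi
  dmc <- phi - shiftCol(phi, 1L)
  gradPlus <- sqrt(pmax(dmr, 0)^2 + pmin(dpr, 0)^2 +
                   pmax(dmc, 0)^2 + pmin(dpc, 0)^2)
  gradMinus <- sqrt(pmin(dmr, 0)^2 + pmax(dpr, 0)^2 +
                    pmin(dmc, 0)^2 + pmax(dpc, 0)^2)
  upd <- params@dt * (pmax(FF, 0) * gradPlus + pmin(FF, 0) * gradMinus)
  if (params@curvature) upd <- upd + params@dt * spf * curvatureOf(phi)
  phi <- gaussSmooth(phi + upd, params@sigmaG)
  if (params@binarize) phi <- ifelse(phi > 0, 1, -1)
  if (!is.null(domain)) phi[!domain] <- -1
  phi
}

#' Binary mask from a level-set field
#'
#' The interior is \code{phi > 0}; exact zeros are exterior.
#'
#' @param phi numeric matrix (finite).
#' @return a logical matrix.
#' @export
maskFromPhi <- function(phi) {
  if (any(!is.finite(phi))) stop("phi contains non-finite values")
  phi > 0
}
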