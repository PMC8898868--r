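## Texture features: gray-level co-occurrence statistics and a dynamic-warping
## distance between boundary radius profiles.
##
## The GLCM counts ordered pairs of quantized gray levels at one pixel offset
## (both pixels inside the region mask), is symmetrized by adding its
## transpose, and normalized to sum to one.  Second-order (Haralick)
## statistics are read off the normalized matrix.  Shape irregularity is
## captured by warping the region's centroid-to-boundary radius profile
## against a reference profile (a unit circle by default) with a
## dynamic-programming minimal-cost monotone alignment.

glcmOffset <- function(p, angle) {
  switch(as.character(angle),
         "0" = c(0L, as.integer(p)),
         "45" = c(-as.integer(p), as.integer(p)),
         "90" = c(-as.integer(p), 0L),
         "135" = c(-as.integer(p), -as.integer(p)),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix over a masked region
#'
#' Intensities (expected in [0, 1]) are quantized to \code{levels} bins by
#' \code{floor(x * L)} (clipped to L-1); ordered level pairs at the given
#' offset whose two pixels both lie in \code{mask} are counted, the count
#' matrix is symmetrized with its transpose and normalized by the total.
#'
#' @param image numeric matrix in [0, 1].
#' @param mask logical matrix (defaults to the whole image).
#' @param levels number of quantization levels (default 16).
#' @param p offset distance in pixels (default 1).
#' @param angle offset angle in degrees: 0, 45, 90 or 135.
#' @return a [GLCM-class].
#' @export
computeGLCM <- function(image, mask = NULL, levels = 16L, p = 1L, angle = 0) {
  checkImage(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- asLogicalMask(mask)
  if (!identical(dim(mask), dim(image))) stop("mask and image shapes differ")
  if (!any(mask)) stop("mask is empty")
  L <- as.integer(levels)
  if (L < 2L) stop("levels must be >= 2")
  lv <- pmin(floor(pmin(pmax(image, 0), 1) * L), L - 1L)

  off <- glcmOffset(p, angle)
  nr <- nrow(image); nc <- ncol(image)
  rows <- seq_len(nr); cols <- seq_len(nc)
  rows <- rows[rows + off[1L] >= 1L & rows + off[1L] <= nr]
  cols <- cols[cols + off[2L] >= 1L & cols + off[2L] <= nc]
  if (!length(rows) || !length(cols))
    stop("offset larger than the image: no valid pixel pairs")
  a <- lv[rows, cols, drop = FALSE]
  b <- lv[rows + off[1L], cols + off[2L], drop = FALSE]
  ok <- mask[rows, cols, drop = FALSE] &
    mask[rows + off[1L], cols + off[2L], drop = FALSE]
  if (!any(ok))
    stop("no valid pixel pairs: mask too thin for offset (p=", p,
         ", angle=", angle, ")")
  counts <- tabulate(a[ok] * L + b[ok] + 1L, nbins = L * L)
  H <- matrix(counts, L, L, byrow = TRUE)  # rows: first pixel level
  H <- H + t(H)
  new("GLCM", levels = L, p = as.integer(p), angle = as.numeric(angle),
      matrix = H / sum(H))
}

#' Second-order texture statistics of a GLCM
#'
#' Entropy \eqn{-\sum q \log_2 q} (with \eqn{0 \log 0 = 0}), contrast
#' \eqn{\sum (n-t)^2 q}, energy \eqn{\sum q^2}, homogeneity
#' \eqn{\sum q/(1+|n-t|)}, and the marginal correlation (defined as 0 when a
#' marginal standard deviation vanishes).
#'
#' @param g a [GLCM-class].
#' @return named numeric vector: entropy, contrast, energy, homogeneity,
#'   correlation.
#' @export
glcmFeatures <- function(g) {
  stopifnot(is(g, "GLCM"))
  q <- g@matrix
  L <- g@levels
  lev <- seq_len(L) - 1
  n <- matrix(lev, L, L)        # row level
  t <- matrix(lev, L, L, byrow = TRUE)
  nz <- q > 0
  entropy <- -sum(q[nz] * log2(q[nz]))
  contrast <- sum((n - t)^2 * q)
  energy <- sum(q^2)
  homogeneity <- sum(q / (1 + abs(n - t)))
  px <- rowSums(q); py <- colSums(q)
  mx <- sum(lev * px); my <- sum(lev * py)
  sx <- sqrt(sum((lev - mx)^2 * px)); sy <- sqrt(sum((lev - my)^2 * py))
  correlation <- if (sx == 0 || sy == 0) 0 else
    (sum(n * t * q) - mx * my) / (sx * sy)
  c(entropy = entropy, contrast = contrast, energy = energy,
    homogeneity = homogeneity, correlation = correlation)
}

#' Centroid-to-boundary radius profile of a region
#'
#' From the region centroid, the distance to the region boundary is measured
#' along \code{nSamples} equally spaced rays (marching in 0.25-pixel steps
#' until the ray leaves the region) and normalized by its mean.  A circle
#' gives a constant profile of 1; boundary irregularity shows up as profile
#' variation.
#'
#' @param mask logical matrix with exactly one connected component.
#' @param nSamples number of rays (default 64).
#' @return numeric vector of \code{nSamples} normalized radii.
#' @export
boundaryProfile <- function(mask, nSamples = 64L) {
  mask <- asLogicalMask(mask)
  if (!any(mask)) stop("mask is empty")
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 1L)
    stop("mask has ", max(lab), " connected components; expected exactly one")
  ctr <- maskCentroid(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  maxT <- sqrt(nr^2 + nc^2)
  step <- 0.25
  th <- 2 * pi * (seq_len(nSamples) - 1L) / nSamples
  inside <- function(t, dr, dc) {
    ri <- round(ctr[1L] + t * dr); ci <- round(ctr[2L] + t * dc)
    ri >= 1 && ri <= nr && ci >= 1 && ci <= nc && mask[ri, ci]
  }
  radii <- vapply(th, function(a) {
    dr <- sin(a); dc <- cos(a)
    t <- 0; last <- 0
    while (t <= maxT) {
      if (!inside(t, dr, dc)) break
      last <- t
      t <- t + step
    }
    if (last >= maxT) return(last)
    lo <- last; hi <- last + step   # refine the exit point by bisection
    for (b in 1:6) {
      mid <- (lo + hi) / 2
      if (inside(mid, dr, dc)) lo <- mid else hi <- mid
    }
    lo
  }, numeric(1))
  m <- mean(radii)
  if (m <= 0) stop("degenerate region: zero mean radius")
  radii / m
}

#' Dynamic-warping distance between two profiles
#'
#' Minimal-cost monotone alignment of \code{a} against \code{b} with unit
#' steps (diagonal, right, down) and cell cost \eqn{|a_i - b_j|}.  Returns
#' the total optimal path cost (\code{dvw}), the mean per-cell cost along the
#' optimal path (\code{localDistance}) and the maximum single-cell cost along
#' it (\code{localCost}).  Ties in the backtrace prefer diagonal, then
#' vertical, then horizontal moves.
#'
#' @param a,b non-empty numeric vectors.
#' @return named numeric vector: dvw, localDistance, localCost.
#' @export
dvwDistance <- function(a, b) {
  if (!length(a) || !length(b)) stop("profiles must be non-empty")
  n <- length(a); m <- length(b)
  cost <- abs(outer(a, b, "-"))
  D <- matrix(Inf, n, m)
  D[1L, 1L] <- cost[1L, 1L]
  for (j in seq_len(m)[-1L]) D[1L, j] <- D[1L, j - 1L] + cost[1L, j]
  for (i in seq_len(n)[-1L]) {
    D[i, 1L] <- D[i - 1L, 1L] + cost[i, 1L]
    if (m > 1L) for (j in 2:m)
      D[i, j] <- cost[i, j] + min(D[i - 1L, j - 1L], D[i - 1L, j], D[i, j - 1L])
  }
  ## backtrace the optimal path (diagonal preferred on ties)
  i <- n; j <- m
  pathCosts <- cost[i, j]
  while (i > 1L || j > 1L) {
    if (i > 1L && j > 1L) {
      cand <- c(D[i - 1L, j - 1L], D[i - 1L, j], D[i, j - 1L])
      mv <- which.min(cand)
      if (mv == 1L) { i <- i - 1L; j <- j - 1L }
      else if (mv == 2L) i <- i - 1L
      else j <- j - 1L
    } else if (i > 1L) i <- i - 1L
    else j <- j - 1L
    pathCosts <- c(pathCosts, cost[i, j])
  }
  c(dvw = D[n, m], localDistance = mean(pathCosts), localCost = max(pathCosts))
}

#' Texture feature vector of a lesion region
#'
#' GLCM statistics averaged over the four offset angles at distance
#' \code{p = 1}, plus the warping distances of the region's boundary profile
#' against a reference profile (a unit circle -- the constant profile 1 -- by
#' default).  When the mask has several components the boundary profile is
#' taken from the largest one; the GLCM uses the whole mask.
#'
#' @param image numeric matrix in [0, 1].
#' @param lesionMask non-empty logical matrix.
#' @param referenceProfile optional reference radius profile.
#' @param levels GLCM quantization levels.
#' @param nSamples boundary profile length.
#' @return named numeric vector: entropy, contrast, energy, homogeneity,
#'   correlation, dvw, localDistance, localCost.
#' @export
extractFeatureVector <- function(image, lesionMask, referenceProfile = NULL,
                                 levels = 16L, nSamples = 64L) {
  checkImage(image)
  lesionMask <- asLogicalMask(lesionMask, "lesionMask")
  if (!any(lesionMask)) stop("lesionMask is empty")
  feats <- NULL
  nOk <- 0L
  for (ang in c(0, 45, 90, 135)) {
    g <- tryCatch(computeGLCM(image, lesionMask, levels = levels, p = 1L,
                              angle = ang),
                  error = function(e) NULL)
    if (is.null(g)) next
    f <- glcmFeatures(g)
    feats <- if (is.null(feats)) f else feats + f
    nOk <- nOk + 1L
  }
  if (nOk == 0L) stop("no GLCM pairs at any angle: region too thin")
  feats <- feats / nOk

  prof <- boundaryProfile(largestComponent(lesionMask), nSamples)
  if (is.null(referenceProfile)) referenceProfile <- rep(1, length(prof))
  c(feats, dvwDistance(prof, referenceProfile))
}
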