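## Thresholded convolutional scorer ("ICNN").
##
## A small conv net -- two 3x3 convolution blocks (same padding, ReLU, 2x2 max
## pooling), a hidden dense layer and a scalar linear head -- trained by Adam
## on a squared loss whose targets straddle the fixed decision threshold:
## benign patches regress toward 1.0 and malignant ones toward 3.0, so a
## trained model's scores naturally fall below / above 2.0.  Optionally the
## texture feature vector is standardized and concatenated to the flattened
## convolutional activations before the dense layers.  Everything is written
## with plain matrix algebra (im2col-style convolutions), runs on one CPU, and
## is bit-reproducible under (dataset, config, seed).

#' Classifier configuration
#'
#' @param patchSize square patch side in pixels (>= 8, divisible by 4).
#' @param convChannels output channels of the two conv blocks.
#' @param denseUnits hidden dense width.
#' @param learningRate Adam step size.
#' @param epochs training epochs.
#' @param batchSize mini-batch size.
#' @param threshold decision threshold (default 2.0).
#' @param useFeatures concatenate texture features to the dense input.
#' @param seed RNG seed for initialization and batch order.
#' @return an [ICNNConfig-class].
#' @export
icnnConfig <- function(patchSize = 16L, convChannels = c(8L, 16L),
                       denseUnits = 32L, learningRate = 5e-3,
                       epochs = 60L, batchSize = 32L, threshold = 2.0,
                       useFeatures = TRUE, seed = 1L) {
  new("ICNNConfig", patchSize = as.integer(patchSize),
      convChannels = as.integer(convChannels),
      denseUnits = as.integer(denseUnits), learningRate = learningRate,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      threshold = threshold, useFeatures = useFeatures,
      seed = as.integer(seed))
}

#' Extract standardized lesion patches
#'
#' One square patch per connected lesion component, centered on the component
#' centroid (rounded), read from the image with reflected borders and
#' intensity-standardized to zero mean and unit variance (constant patches
#' become all-zero).
#'
#' @param image numeric matrix.
#' @param lesionMask non-empty logical matrix.
#' @param patchSize patch side in pixels.
#' @return a list of patchSize x patchSize matrices, one per component.
#' @export
makePatches <- function(image, lesionMask, patchSize = 16L) {
  checkImage(image)
  lesionMask <- asLogicalMask(lesionMask, "lesionMask")
  if (!any(lesionMask)) stop("lesionMask is empty")
  patchSize <- as.integer(patchSize)
  lab <- EBImage::bwlabel(lesionMask)
  nr <- nrow(image); nc <- ncol(image)
  refl <- function(i, n) {
    while (any(i < 1L | i > n)) {
      i[i < 1L] <- 2L - i[i < 1L]
      i[i > n] <- 2L * n - i[i > n]
    }
    i
  }
  lapply(seq_len(max(lab)), function(k) {
    ctr <- round(maskCentroid(lab == k))
    rows <- refl(ctr[1L] - patchSize %/% 2L + seq_len(patchSize) - 1L, nr)
    cols <- refl(ctr[2L] - patchSize %/% 2L + seq_len(patchSize) - 1L, nc)
    p <- image[rows, cols, drop = FALSE]
    s <- sd(p)
    if (!is.finite(s) || s < 1e-12) return(p * 0)
    (p - mean(p)) / s
  })
}

## ---- network internals ------------------------------------------------------

## geometry of one conv(3x3, same) + pool(2x2) block on an h x h grid:
## IDX[o, k]: padded linear index of neighbor k for output position o
## INT[o]  : padded linear index of interior position o
## POOL[q, 1:4]: positions pooled into output q
convGeometry <- function(h) {
  hp <- h + 2L
  pos <- expand.grid(r = seq_len(h), c = seq_len(h))       # column-major grid
  INT <- (pos$c) * hp + pos$r + 1L                          # (r+1, c+1) in pad
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  IDX <- sapply(seq_len(9L), function(k)
    (pos$c + offs$dc[k]) * hp + (pos$r + offs$dr[k]) + 1L)
  ho <- h %/% 2L
  opos <- expand.grid(r = seq_len(ho), c = seq_len(ho))
  POOL <- sapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                 function(d) (2L * (opos$c - 1L) + d[2L]) * h +
                   (2L * (opos$r - 1L) + d[1L]) + 1L)
  list(h = h, hp = hp, INT = INT, IDX = IDX, POOL = POOL)
}

## A: array [n, h*h, Cin] -> list(Z = [n, h*h, Cout], cache)
convForward <- function(A, W, b, geom) {
  n <- dim(A)[1L]; hw <- dim(A)[2L]; cin <- dim(A)[3L]
  cout <- length(b)
  Apad <- array(0, c(n, geom$hp^2, cin))
  Apad[, geom$INT, ] <- A
  Acol <- array(0, c(n, hw, 9L * cin))
  for (k in seq_len(9L))
    Acol[, , ((k - 1L) * cin + 1L):(k * cin)] <- Apad[, geom$IDX[, k], ,
                                                      drop = FALSE]
  dim(Acol) <- c(n * hw, 9L * cin)
  Z <- Acol %*% W
  Z <- sweep(Z, 2L, b, "+")
  dim(Z) <- c(n, hw, cout)
  list(Z = Z, Acol = Acol)
}

convBackward <- function(dZ, cache, W, geom, n, cin) {
  hw <- dim(dZ)[2L]; cout <- dim(dZ)[3L]
  dZm <- dZ; dim(dZm) <- c(n * hw, cout)
  dW <- crossprod(cache$Acol, dZm)
  db <- colSums(dZm)
  dAcol <- dZm %*% t(W)
  dim(dAcol) <- c(n, hw, 9L * cin)
  dApad <- array(0, c(n, geom$hp^2, cin))
  for (k in seq_len(9L))
    dApad[, geom$IDX[, k], ] <- dApad[, geom$IDX[, k], , drop = FALSE] +
      dAcol[, , ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
  dA <- dApad[, geom$INT, , drop = FALSE]
  list(dA = dA, dW = dW, db = db)
}

poolForward <- function(A, geom) {
  M <- A[, geom$POOL[, 1L], , drop = FALSE]
  AMAX <- array(1L, dim(M))
  for (k in 2:4) {
    cand <- A[, geom$POOL[, k], , drop = FALSE]
    upd <- cand > M
    M[upd] <- cand[upd]
    AMAX[upd] <- k
  }
  list(M = M, AMAX = AMAX)
}

poolBackward <- function(dM, cache, geom, hw) {
  dA <- array(0, c(dim(dM)[1L], hw, dim(dM)[3L]))
  for (k in 1:4)
    dA[, geom$POOL[, k], ] <- dA[, geom$POOL[, k], ] + dM * (cache$AMAX == k)
  dA
}

icnnGeometry <- function(cfg) {
  list(g1 = convGeometry(cfg@patchSize),
       g2 = convGeometry(cfg@patchSize %/% 2L),
       flat = (cfg@patchSize %/% 4L)^2 * cfg@convChannels[2L])
}

icnnInitWeights <- function(cfg, nFeat) {
  c1 <- cfg@convChannels[1L]; c2 <- cfg@convChannels[2L]
  geom <- icnnGeometry(cfg)
  nd <- geom$flat + nFeat
  he <- function(fanIn, nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / fanIn)), nr, nc)
  list(W1 = he(9, 9L, c1), b1 = rep(0, c1),
       W2 = he(9 * c1, 9L * c1, c2), b2 = rep(0, c2),
       W3 = he(nd, nd, cfg@denseUnits), b3 = rep(0, cfg@denseUnits),
       W4 = he(cfg@denseUnits, cfg@denseUnits, 1L), b4 = 0)
}

## X: array [n, p*p]; Fm: matrix [n, nFeat] or NULL
icnnForwardFull <- function(w, X, Fm, cfg, geom) {
  n <- nrow(X)
  A0 <- array(X, c(n, ncol(X), 1L))
  cv1 <- convForward(A0, w$W1, w$b1, geom$g1)
  R1 <- pmax(cv1$Z, 0)
  p1 <- poolForward(R1, geom$g1)
  cv2 <- convForward(p1$M, w$W2, w$b2, geom$g2)
  R2 <- pmax(cv2$Z, 0)
  p2 <- poolForward(R2, geom$g2)
  Fl <- p2$M; dim(Fl) <- c(n, geom$flat)
  D <- if (is.null(Fm)) Fl else cbind(Fl, Fm)
  Z3 <- sweep(D %*% w$W3, 2L, w$b3, "+")
  R3 <- pmax(Z3, 0)
  s <- as.numeric(R3 %*% w$W4 + w$b4)
  list(s = s, A0 = A0, cv1 = cv1, R1 = R1, p1 = p1, cv2 = cv2, R2 = R2,
       p2 = p2, D = D, Z3 = Z3, R3 = R3)
}

icnnBackwardFull <- function(w, fw, ds, cfg, geom, nFeat) {
  n <- length(ds)
  dW4 <- crossprod(fw$R3, matrix(ds, n, 1L))
  db4 <- sum(ds)
  dR3 <- matrix(ds, n, 1L) %*% t(w$W4)
  dZ3 <- dR3 * (fw$Z3 > 0)
  dW3 <- crossprod(fw$D, dZ3)
  db3 <- colSums(dZ3)
  dD <- dZ3 %*% t(w$W3)
  dFl <- dD[, seq_len(geom$flat), drop = FALSE]
  dP2 <- array(dFl, c(n, (cfg@patchSize %/% 4L)^2, cfg@convChannels[2L]))
  h2 <- cfg@patchSize %/% 2L
  dR2 <- poolBackward(dP2, fw$p2, geom$g2, h2^2)
  dZ2 <- dR2 * (fw$cv2$Z > 0)
  bk2 <- convBackward(dZ2, fw$cv2, w$W2, geom$g2, n, cfg@convChannels[1L])
  dR1 <- poolBackward(bk2$dA, fw$p1, geom$g1, cfg@patchSize^2)
  dZ1 <- dR1 * (fw$cv1$Z > 0)
  bk1 <- convBackward(dZ1, fw$cv1, w$W1, geom$g1, n, 1L)
  list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

#' Train the thresholded convolutional scorer
#'
#' \code{dataset} is a list of items, each a list with elements \code{patch}
#' (a standardized square matrix, see [makePatches()]), optional
#' \code{features} (the [extractFeatureVector()] vector) and \code{label}
#' (\code{"benign"} or \code{"malignant"}).  Training minimizes the squared
#' distance of scores to class targets placed symmetrically around the
#' decision threshold (threshold - 1 for benign, threshold + 1 for
#' malignant; 1.0 and 3.0 at the default threshold 2.0) with Adam.  Fully
#' reproducible under (dataset, config, seed).
#'
#' @param dataset list of items as above; both classes must be present.
#' @param config an [ICNNConfig-class].
#' @return an [ICNNModel-class].
#' @export
trainICNN <- function(dataset, config = icnnConfig()) {
  validObject(config)
  n <- length(dataset)
  if (n < 2L) stop("dataset must contain at least 2 items")
  labels <- vapply(dataset, function(d) d$label, character(1))
  if (!all(labels %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'")
  if (length(unique(labels)) < 2L)
    stop("dataset contains a single class; both classes are required")
  ps <- config@patchSize
  X <- t(vapply(dataset, function(d) {
    if (!identical(dim(d$patch), c(ps, ps)))
      stop("patch shape does not match config patchSize")
    as.numeric(d$patch)
  }, numeric(ps * ps)))
  Fm <- NULL; ctr <- numeric(0); scl <- numeric(0)
  if (config@useFeatures) {
    Fm <- t(vapply(dataset, function(d) {
      if (is.null(d$features)) stop("useFeatures is on but an item has none")
      as.numeric(d$features)
    }, numeric(length(dataset[[1L]]$features))))
    ctr <- colMeans(Fm)
    scl <- apply(Fm, 2L, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    Fm <- sweep(sweep(Fm, 2L, ctr), 2L, scl, "/")
  }
  target <- ifelse(labels == "malignant", config@threshold + 1,
                   config@threshold - 1)
  geom <- icnnGeometry(config)
  nFeat <- if (is.null(Fm)) 0L else ncol(Fm)

  log <- numeric(config@epochs)
  w <- withr::with_seed(config@seed, {
    w <- icnnInitWeights(config, nFeat)
    mAdam <- lapply(w, function(x) x * 0)
    vAdam <- lapply(w, function(x) x * 0)
    step <- 0L
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
    for (ep in seq_len(config@epochs)) {
      ord <- sample(n)
      lossAcc <- 0
      for (start in seq(1L, n, by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1L, n)]
        fw <- icnnForwardFull(w, X[idx, , drop = FALSE],
                              if (is.null(Fm)) NULL else Fm[idx, , drop = FALSE],
                              config, geom)
        err <- fw$s - target[idx]
        lossAcc <- lossAcc + sum(err^2)
        ds <- 2 * err / length(idx)
        gr <- icnnBackwardFull(w, fw, ds, config, geom, nFeat)
        step <- step + 1L
        for (nm in names(w)) {
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * gr[[nm]]
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * gr[[nm]]^2
          mh <- mAdam[[nm]] / (1 - b1^step)
          vh <- vAdam[[nm]] / (1 - b2^step)
          w[[nm]] <- w[[nm]] - config@learningRate * mh / (sqrt(vh) + epsA)
        }
      }
      log[ep] <- lossAcc / n
    }
    w
  })
  new("ICNNModel", config = config, weights = w,
      featureCenter = ctr, featureScale = scl, trainingLog = log)
}

#' Score a lesion patch
#'
#' Deterministic forward pass of a trained model; no thresholding is applied.
#'
#' @param model an [ICNNModel-class].
#' @param patch a standardized patchSize x patchSize matrix.
#' @param features texture feature vector (required iff the model was trained
#'   with \code{useFeatures}).
#' @return a finite scalar score.
#' @seealso [predictLabel()]
#' @export
scoreICNN <- function(model, patch, features = NULL) {
  stopifnot(is(model, "ICNNModel"))
  cfg <- model@config
  ps <- cfg@patchSize
  if (!identical(dim(patch), c(ps, ps)))
    stop("patch shape ", paste(dim(patch), collapse = "x"),
         " does not match config patchSize ", ps)
  Fm <- NULL
  if (cfg@useFeatures) {
    if (is.null(features)) stop("model was trained with features; none given")
    if (length(features) != length(model@featureCenter))
      stop("feature vector length does not match the trained model")
    Fm <- matrix((as.numeric(features) - model@featureCenter) /
                   model@featureScale, 1L)
  }
  geom <- icnnGeometry(cfg)
  icnnForwardFull(model@weights, matrix(as.numeric(patch), 1L), Fm,
                  cfg, geom)$s
}

#' Threshold a score into a class label
#'
#' Scores strictly above the threshold are malignant, scores at or below it
#' benign (the tie goes to benign).
#'
#' @param s numeric score(s), finite.
#' @param threshold decision threshold (default 2.0).
#' @return character vector of \code{"benign"} / \code{"malignant"}.
#' @export
predictLabel <- function(s, threshold = 2.0) {
  if (any(!is.finite(s))) stop("scores must be finite")
  ifelse(s > threshold, "malignant", "benign")
}
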