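## Independent brute-force oracles used across the suite.  These stay naive
## on purpose: direct summation, exhaustive enumeration, no shared code with
## the implementation paths they check.

## GLCM by pixel-by-pixel pair enumeration (ordered pairs, then symmetrized)
bruteGLCM <- function(image, mask, levels, p, angle) {
  off <- switch(as.character(angle),
                "0" = c(0L, p), "45" = c(-p, p), "90" = c(-p, 0L),
                "135" = c(-p, -p))
  lv <- pmin(floor(pmin(pmax(image, 0), 1) * levels), levels - 1L)
  H <- matrix(0, levels, levels)
  nr <- nrow(image); nc <- ncol(image)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + off[1L]; j2 <- j + off[2L]
    if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
    if (!mask[i, j] || !mask[i2, j2]) next
    H[lv[i, j] + 1L, lv[i2, j2] + 1L] <- H[lv[i, j] + 1L, lv[i2, j2] + 1L] + 1
  }
  H <- H + t(H)
  if (sum(H) == 0) return(NULL)
  H / sum(H)
}

## GLCM statistics by a naive double loop over matrix cells
bruteGLCMFeatures <- function(q) {
  L <- nrow(q)
  entropy <- 0; contrast <- 0; energy <- 0; homog <- 0
  for (n in 1:L) for (t in 1:L) {
    v <- q[n, t]
    if (v > 0) entropy <- entropy - v * log2(v)
    contrast <- contrast + ((n - 1) - (t - 1))^2 * v
    energy <- energy + v^2
    homog <- homog + v / (1 + abs(n - t))
  }
  px <- rowSums(q); py <- colSums(q); lev <- 0:(L - 1)
  mx <- sum(lev * px); my <- sum(lev * py)
  sx <- sqrt(sum((lev - mx)^2 * px)); sy <- sqrt(sum((lev - my)^2 * py))
  corr <- 0
  if (sx > 0 && sy > 0) {
    acc <- 0
    for (n in 1:L) for (t in 1:L) acc <- acc + (n - 1) * (t - 1) * q[n, t]
    corr <- (acc - mx * my) / (sx * sy)
  }
  c(entropy = entropy, contrast = contrast, energy = energy,
    homogeneity = homog, correlation = corr)
}

## every monotone path from (1,1) to (n,m) with steps diag/down/right,
## returning the minimal summed |a_i - b_j| and the per-path cell costs of
## every optimal path (for checking the reported local statistics)
brutePaths <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  bestPaths <- list()
  walk <- function(i, j, costs) {
    costs <- c(costs, abs(a[i] - b[j]))
    if (i == n && j == m) {
      tot <- sum(costs)
      if (tot < best - 1e-12) {
        best <<- tot; bestPaths <<- list(costs)
      } else if (abs(tot - best) <= 1e-12) {
        bestPaths[[length(bestPaths) + 1L]] <<- costs
      }
      return(invisible(NULL))
    }
    if (i < n && j < m) walk(i + 1L, j + 1L, costs)
    if (i < n) walk(i + 1L, j, costs)
    if (j < m) walk(i, j + 1L, costs)
  }
  walk(1L, 1L, numeric(0))
  list(dvw = best, paths = bestPaths)
}

## confusion counts by explicit looping
bruteConfusion <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == "malignant" && pred[i] == "malignant") tp <- tp + 1L
    if (truth[i] == "benign" && pred[i] == "malignant") fp <- fp + 1L
    if (truth[i] == "benign" && pred[i] == "benign") tn <- tn + 1L
    if (truth[i] == "malignant" && pred[i] == "benign") fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

## AUC as the normalized pairwise comparison count (Mann-Whitney U with ties)
bruteAUC <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (x in sp) for (y in sn)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(sp) * length(sn))
}

## small standard phantom used across segmentation tests
standardPhantom <- function(seed, nLesions = 0, label = "benign", ...) {
  makePhantom(phantomSpec(nLesions = nLesions, label = label, seed = seed, ...))
}
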