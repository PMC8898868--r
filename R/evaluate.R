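## Evaluation layer: confusion counts, the derived classification metrics,
## exact binomial intervals, ROC/AUC and mask-overlap scores.  Malignant is
## the positive class throughout.  Metrics with a zero denominator are
## reported as NA (explicitly undefined), never coerced to 0.

normalizeLabels <- function(x, what) {
  if (is.logical(x)) return(ifelse(x, "malignant", "benign"))
  x <- as.character(x)
  if (!all(x %in% c("benign", "malignant")))
    stop(what, " must be logical or 'benign'/'malignant'")
  x
}

#' Confusion counts for benign/malignant predictions
#'
#' Counts TP/FP/TN/FN with malignant as the positive class.  Inputs may be
#' character vectors of \code{"benign"}/\code{"malignant"} or logicals
#' (\code{TRUE} = malignant).
#'
#' @param truth,pred equal-length label vectors.
#' @return a [ConfusionMatrix-class].
#' @export
confusionCounts <- function(truth, pred) {
  if (length(truth) != length(pred) || length(truth) < 1L)
    stop("truth and pred must have equal length >= 1")
  truth <- normalizeLabels(truth, "truth")
  pred <- normalizeLabels(pred, "pred")
  tpos <- truth == "malignant"; ppos <- pred == "malignant"
  new("ConfusionMatrix",
      tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
      tn = sum(!tpos & !ppos), fn = sum(tpos & !ppos))
}

#' Sensitivity, specificity, accuracy and PPV from confusion counts
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/total, PPV = TP/(TP+FP).  A metric whose denominator is
#' zero is returned as \code{NA} (undefined).
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named numeric vector: sensitivity, specificity, accuracy, ppv.
#' @export
classificationMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  validObject(cm)
  rat <- function(num, den) if (den == 0L) NA_real_ else num / den
  c(sensitivity = rat(cm@tp, cm@tp + cm@fn),
    specificity = rat(cm@tn, cm@tn + cm@fp),
    accuracy = rat(cm@tp + cm@tn, cm@tp + cm@fp + cm@tn + cm@fn),
    ppv = rat(cm@tp, cm@tp + cm@fp))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact two-sided interval for a proportion, from beta quantiles; the
#' lower bound is exactly 0 when \code{successes == 0} and the upper bound
#' exactly 1 when \code{successes == trials}.
#'
#' @param successes,trials non-negative counts with
#'   \code{0 <= successes <= trials}, \code{trials >= 1}.
#' @param level confidence level in (0, 1), default 0.95.
#' @return named numeric vector: lower, upper.
#' @export
accuracyCI <- function(successes, trials, level = 0.95) {
  if (trials < 1L) stop("trials must be >= 1")
  if (successes < 0L || successes > trials)
    stop("successes must lie in [0, trials]")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  a <- (1 - level) / 2
  lower <- if (successes == 0L) 0 else qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else qbeta(1 - a, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' ROC curve and trapezoid AUC
#'
#' Sweeps thresholds over the unique scores (higher score = more malignant),
#' with (0, 0) prepended; the AUC is the trapezoid area, which equals the
#' tie-corrected normalized Mann-Whitney U statistic.
#'
#' @param scores numeric scores.
#' @param labels truth labels (logical or \code{"benign"}/\code{"malignant"});
#'   both classes must be present.
#' @return a [RocCurve-class].
#' @export
rocCurve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- normalizeLabels(labels, "labels") == "malignant"
  if (!any(pos) || all(pos))
    stop("labels contain a single class; ROC needs both")
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]; po <- pos[ord]
  tps <- cumsum(po); fps <- cumsum(!po)
  last <- which(c(diff(sc) != 0, TRUE))  # last index within each tied block
  P <- sum(pos); N <- sum(!pos)
  tpr <- c(0, tps[last] / P)
  fpr <- c(0, fps[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  new("RocCurve", thresholds = c(Inf, sc[last]), tpr = tpr, fpr = fpr,
      auc = auc)
}

#' Dice and Jaccard overlap of two binary masks
#'
#' dice = 2|a & b| / (|a| + |b|), jaccard = |a & b| / |a | b|; both are 1 by
#' convention when both masks are empty.
#'
#' @param a,b logical (or 0/1 numeric) matrices of one shape.
#' @return named numeric vector: dice, jaccard.
#' @export
overlapMetrics <- function(a, b) {
  a <- asLogicalMask(a, "a"); b <- asLogicalMask(b, "b")
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  inter <- sum(a & b); uni <- sum(a | b); sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(c(dice = 1, jaccard = 1))
  c(dice = 2 * inter / (sa + sb), jaccard = inter / uni)
}

#' @rdname overlapMetrics
#' @export
dice <- function(a, b) unname(overlapMetrics(a, b)["dice"])

#' @rdname overlapMetrics
#' @export
jaccard <- function(a, b) unname(overlapMetrics(a, b)["jaccard"])
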