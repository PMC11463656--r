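#' Threshold a probability map
#'
#' @param prob numeric matrix with values in \[0, 1\].
#' @param threshold inclusive cut: values >= threshold become 1.
#' @return logical matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE))
    stop("probability map values must lie in [0, 1]")
  prob >= threshold
}

#' Pixel-wise agreement map
#'
#' Classifies every pixel of a prediction against ground truth:
#' TP (gt 1, pred 1), FP (gt 0, pred 1), FN (gt 1, pred 0), TN (both 0).
#'
#' @param gt,pred logical (or 0/1) matrices of equal dims.
#' @param threshold stored on the result for provenance.
#' @return object of class `AgreementMap`: list(map (integer matrix
#'   coded 0 TN / 1 TP / 2 FP / 3 FN), counts (tp, fp, fn, tn),
#'   threshold).
#' @export
agreement_map <- function(gt, pred, threshold = 0.5) {
  if (!all(dim(gt) == dim(pred))) stop("gt and pred dims differ")
  g <- gt > 0; p <- pred > 0
  map <- matrix(0L, nrow(g), ncol(g))
  map[g & p] <- 1L
  map[!g & p] <- 2L
  map[g & !p] <- 3L
  counts <- c(tp = sum(map == 1L), fp = sum(map == 2L),
              fn = sum(map == 3L), tn = sum(map == 0L))
  structure(list(map = map, counts = counts, threshold = threshold),
            class = "AgreementMap")
}

#' @export
print.AgreementMap <- function(x, ...) {
  cat(sprintf("AgreementMap %d x %d: tp %d, fp %d, fn %d, tn %d\n",
              nrow(x$map), ncol(x$map), x$counts["tp"], x$counts["fp"],
              x$counts["fn"], x$counts["tn"]))
  invisible(x)
}

.zero_warn <- function(what) {
  warning(sprintf("%s undefined (zero denominator); reporting 0", what))
  0
}

#' Pixel-level segmentation scores
#'
#' Precision, recall, F1, positive and negative IOU and their mean
#' (mIOU), from an [agreement_map()], a named count vector, or a
#' (gt, pred) pair. mIOU is the average of positive-class IOU
#' tp/(tp+fp+fn) and negative-class IOU tn/(tn+fp+fn). Zero
#' denominators yield 0 with a warning.
#'
#' @param x an `AgreementMap`, a named numeric vector with tp/fp/fn/tn,
#'   or a gt matrix (then supply `pred`).
#' @param pred prediction matrix when `x` is a ground-truth matrix.
#' @return object of class `PixelScores` (named list).
#' @export
pixel_scores <- function(x, pred = NULL) {
  counts <- if (inherits(x, "AgreementMap")) x$counts
            else if (is.numeric(x) && !is.null(names(x))) x
            else agreement_map(x, pred)$counts
  if (any(counts < 0)) stop("counts must be non-negative")
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  precision <- if (tp + fp > 0) tp / (tp + fp) else .zero_warn("precision")
  recall <- if (tp + fn > 0) tp / (tp + fn) else .zero_warn("recall")
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  piou <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else .zero_warn("positive IOU")
  niou <- if (tn + fp + fn > 0) tn / (tn + fp + fn) else .zero_warn("negative IOU")
  structure(
    list(precision = precision, recall = recall, f1 = f1,
         positive_iou = piou, negative_iou = niou,
         miou = (piou + niou) / 2, counts = counts),
    class = "PixelScores")
}

#' @export
print.PixelScores <- function(x, ...) {
  cat(sprintf(
    "PixelScores: precision %.4f, recall %.4f, F1 %.4f, mIOU %.4f (pIOU %.4f, nIOU %.4f)\n",
    x$precision, x$recall, x$f1, x$miou, x$positive_iou, x$negative_iou))
  invisible(x)
}

#' Tversky index
#'
#' TP / (TP + alpha FN + beta FP); alpha = beta = 0.5 recovers F1
#' (Dice). Weighting alpha > beta penalises missed tangle pixels more
#' than false alarms.
#'
#' @param counts named vector with tp, fp, fn (e.g. from
#'   [agreement_map()]).
#' @param alpha,beta false-negative and false-positive weights.
#' @return scalar in \[0, 1\].
#' @export
tversky <- function(counts, alpha = 0.5, beta = 0.5) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  den <- tp + alpha * fn + beta * fp
  if (den == 0) return(.zero_warn("Tversky index"))
  tp / den
}

#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney U statistic with midrank tie
#' handling: the probability that a random positive pixel scores above
#' a random negative one (ties counting one half).
#'
#' @param gt binary vector (or matrix, flattened).
#' @param scores numeric vector of the same length.
#' @return scalar AUROC.
#' @export
auroc <- function(gt, scores) {
  g <- as.vector(gt) > 0
  s <- as.vector(scores)
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: ground truth contains a single class")
  r <- rank(s, ties.method = "average")
  (sum(r[g]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Prevalence-based random F1 baseline
#'
#' F1 of a null model whose precision equals the positive-pixel
#' prevalence of the evaluation set and whose recall is fixed
#' (default 0.5): 2PR / (P + R).
#'
#' @param prevalence positive-class prevalence, in (0, 1).
#' @param recall assumed null-model recall.
#' @return scalar baseline F1.
#' @export
random_baseline_f1 <- function(prevalence, recall = 0.5) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)")
  2 * prevalence * recall / (prevalence + recall)
}

#' Overlay an agreement map on an RGB image
#'
#' Alpha-blends TP pixels cyan, FP yellow and FN magenta over the
#' source image; TN pixels are untouched.
#'
#' @param rgb H x W x 3 array, 0..255.
#' @param am an `AgreementMap` with matching dims.
#' @param alpha blend weight of the category colour.
#' @return H x W x 3 integer array.
#' @export
render_agreement_overlay <- function(rgb, am, alpha = 0.5) {
  .check_rgb(rgb)
  if (!all(dim(rgb)[1:2] == dim(am$map))) stop("overlay dims mismatch")
  pal <- rbind(tp = c(0, 255, 255), fp = c(255, 255, 0), fn = c(255, 0, 255))
  out <- rgb * 1.0
  for (k in 1:3) {           # 1 TP, 2 FP, 3 FN
    sel <- am$map == k
    if (!any(sel)) next
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[sel] <- (1 - alpha) * pl[sel] + alpha * pal[k, ch]
      out[, , ch] <- pl
    }
  }
  out <- round(out)
  storage.mode(out) <- "integer"
  out
}

#' Per-object IOU of a predicted mask against truth masks
#'
#' For each ground-truth object mask, the IOU between the truth and the
#' union of predicted-mask connected components intersecting it
#' (so neighbouring objects' pixels do not penalise an otherwise exact
#' recovery).
#'
#' @param truth_masks list of logical H x W truth masks.
#' @param pred logical H x W predicted mask.
#' @param connectivity component connectivity for the prediction.
#' @return numeric vector of IOUs, one per truth mask.
#' @export
per_object_iou <- function(truth_masks, pred, connectivity = 8) {
  lab <- label_components(pred > 0, connectivity)
  vapply(truth_masks, function(tm) {
    hits <- unique(lab[tm & lab > 0])
    if (length(hits) == 0) return(0)
    pm <- matrix(lab %in% hits, nrow(lab), ncol(lab))
    sum(pm & tm) / sum(pm | tm)
  }, numeric(1))
}
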