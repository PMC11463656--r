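# Shared fixture builders; everything is generated in code at test time.

# binary disk mask on an H x W canvas, 0-based centre (cx, cy)
disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# quick box constructor
bb <- function(xmin, ymin, xmax, ymax, conf = NA_real_) {
  bounding_boxes(xmin, ymin, xmax, ymax, confidence = conf)
}

# brute-force per-pixel confusion counts
brute_counts <- function(gt, pred) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    g <- gt[i, j] > 0; p <- pred[i, j] > 0
    if (g && p) tp <- tp + 1L
    else if (!g && p) fp <- fp + 1L
    else if (g && !p) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# O(n^2) pairwise AUROC oracle (midrank tie handling)
brute_auroc <- function(gt, scores) {
  pos <- scores[gt > 0]; neg <- scores[gt == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# independent greedy matcher over the sorted IOU pair list
brute_greedy_match <- function(gt, pred, min_iou) {
  iou <- box_iou(gt, pred)
  cand <- expand.grid(g = seq_len(nrow(gt)), p = seq_len(nrow(pred)))
  cand$iou <- iou[cbind(cand$g, cand$p)]
  cand <- cand[order(-cand$iou), , drop = FALSE]
  gu <- rep(FALSE, nrow(gt)); pu <- rep(FALSE, nrow(pred))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    if (cand$iou[k] < min_iou || cand$iou[k] <= 0) break
    if (gu[cand$g[k]] || pu[cand$p[k]]) next
    gu[cand$g[k]] <- TRUE; pu[cand$p[k]] <- TRUE
    pairs[[length(pairs) + 1]] <- cand[k, ]
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
       n_match = length(pairs), fp = sum(!pu), fn = sum(!gu))
}

# brute-force greedy NMS
brute_nms <- function(boxes, thr) {
  ord <- order(boxes$confidence, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in keep)
      if (box_iou(boxes[i, , drop = FALSE],
                  boxes[k, , drop = FALSE])[1, 1] > thr) ok <- FALSE
    if (ok) keep <- c(keep, i)
  }
  boxes[sort(keep), , drop = FALSE]
}

# random box set on a canvas
random_boxes <- function(n, lim = 100, conf = FALSE) {
  x0 <- runif(n, 0, lim - 10); y0 <- runif(n, 0, lim - 10)
  w <- runif(n, 3, 30); h <- runif(n, 3, 30)
  bounding_boxes(x0, y0, x0 + w, y0 + h,
                 confidence = if (conf) runif(n) else NA_real_)
}
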