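#' Construct a bounding-box table
#'
#' Boxes are axis-aligned with half-open, 0-based pixel coordinates:
#' a box covers columns \[xmin, xmax) and rows \[ymin, ymax), so its
#' pixel area is (xmax - xmin) * (ymax - ymin).
#'
#' @param xmin,ymin,xmax,ymax numeric vectors.
#' @param confidence optional confidences in \[0, 1\].
#' @param label integer class label (0 = NFT).
#' @return data.frame of class `BoundingBox`.
#' @export
bounding_boxes <- function(xmin, ymin, xmax, ymax, confidence = NA_real_,
                           label = 0L) {
  if (any(xmin >= xmax) || any(ymin >= ymax))
    stop("degenerate box: xmin < xmax and ymin < ymax required")
  out <- data.frame(label = as.integer(label), xmin = xmin, ymin = ymin,
                    xmax = xmax, ymax = ymax, confidence = confidence)
  class(out) <- c("BoundingBox", class(out))
  out
}

.empty_boxes <- function() {
  bb <- data.frame(label = integer(0), xmin = numeric(0), ymin = numeric(0),
                   xmax = numeric(0), ymax = numeric(0),
                   confidence = numeric(0))
  class(bb) <- c("BoundingBox", class(bb))
  bb
}

#' Pairwise IOU between two box sets
#'
#' @param a,b `BoundingBox` data.frames.
#' @return nrow(a) x nrow(b) matrix of intersection-over-union values
#'   on pixel-area semantics.
#' @export
box_iou <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(0, nrow(a), nrow(b)))
  ix <- pmax(0, outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax))
  iy <- pmax(0, outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax))
  inter <- ix * iy
  area_a <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  area_b <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  inter / (outer(area_a, area_b, "+") - inter)
}

#' Bounding boxes of mask connected components
#'
#' One tight box per connected component of a binary mask.
#'
#' @param mask logical matrix.
#' @param connectivity component connectivity.
#' @return `BoundingBox` data.frame (empty for an empty mask).
#' @export
masks_to_boxes <- function(mask, connectivity = 8) {
  lab <- label_components(mask > 0, connectivity)
  n <- max(lab)
  if (n == 0) return(.empty_boxes())
  idx <- which(lab > 0)
  lv <- lab[idx]
  rows <- (idx - 1) %% nrow(lab)    # 0-based y
  cols <- (idx - 1) %/% nrow(lab)   # 0-based x
  bounding_boxes(
    xmin = as.numeric(tapply(cols, lv, min)),
    ymin = as.numeric(tapply(rows, lv, min)),
    xmax = as.numeric(tapply(cols, lv, max)) + 1,
    ymax = as.numeric(tapply(rows, lv, max)) + 1)
}

.box_centers <- function(b) {
  cbind((b$xmin + b$xmax) / 2, (b$ymin + b$ymax) / 2)
}

#' Merge nearby bounding boxes
#'
#' Boxes whose centre-to-centre distance is at most `center_dist` px
#' are merged into their common enclosing box. Merging acts on the
#' transitive closure of the proximity graph (chains collapse) and is
#' iterated to a fixpoint, so the result is deterministic,
#' order-independent and idempotent. Merged boxes keep the maximum
#' confidence of their members.
#'
#' @param boxes `BoundingBox` data.frame.
#' @param center_dist merge radius, px (default 150).
#' @return merged `BoundingBox` data.frame.
#' @export
merge_boxes <- function(boxes, center_dist = 150) {
  if (nrow(boxes) <= 1) return(boxes)
  repeat {
    ctr <- .box_centers(boxes)
    d <- as.matrix(stats::dist(ctr))
    adj <- d <= center_dist
    # union-find over the proximity graph
    parent <- seq_len(nrow(boxes))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nrow(boxes) - 1)) for (j in (i + 1):nrow(boxes))
      if (adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    comp <- vapply(seq_len(nrow(boxes)), find, integer(1))
    if (length(unique(comp)) == nrow(boxes)) return(boxes)
    merged <- do.call(rbind, lapply(unique(comp), function(k) {
      b <- boxes[comp == k, , drop = FALSE]
      data.frame(label = b$label[1], xmin = min(b$xmin), ymin = min(b$ymin),
                 xmax = max(b$xmax), ymax = max(b$ymax),
                 confidence = suppressWarnings(max(b$confidence)))
    }))
    class(merged) <- class(boxes)
    boxes <- merged
  }
}

#' Ground-truth boxes from an ROI mask and its point annotations
#'
#' For each point, the extent (min/max coordinates) of mask foreground
#' within the `crop` x `crop` window centred on the point, shifted back
#' to the ROI frame — consistent with the tile size used to bootstrap
#' the masks. Points whose window holds no foreground yield no box and
#' are reported via the `empty_points` attribute.
#'
#' @param mask logical ROI mask.
#' @param points data.frame with `x`, `y` (0-based ROI coords).
#' @param crop window edge, px (default 400).
#' @return `BoundingBox` data.frame with attribute `empty_points`
#'   (input row indices that produced no box).
#' @export
gt_boxes_from_points <- function(mask, points, crop = 400) {
  d <- dim(mask)
  half <- crop %/% 2
  res <- list(); empty <- integer(0)
  for (i in seq_len(nrow(points))) {
    x <- round(points$x[i]); y <- round(points$y[i])
    xs <- max(0, x - half):min(d[2] - 1, x + half - 1)
    ys <- max(0, y - half):min(d[1] - 1, y + half - 1)
    win <- mask[ys + 1, xs + 1, drop = FALSE]
    if (!any(win)) { empty <- c(empty, i); next }
    idx <- which(win, arr.ind = TRUE)
    res[[length(res) + 1L]] <- data.frame(
      label = 0L,
      xmin = xs[1] + min(idx[, 2]) - 1, ymin = ys[1] + min(idx[, 1]) - 1,
      xmax = xs[1] + max(idx[, 2]), ymax = ys[1] + max(idx[, 1]),
      confidence = NA_real_)
  }
  out <- if (length(res)) do.call(rbind, res) else .empty_boxes()
  class(out) <- c("BoundingBox", setdiff(class(out), "BoundingBox"))
  attr(out, "empty_points") <- empty
  out
}

#' Greedy IOU matching of predicted against ground-truth boxes
#'
#' Candidate pairs are taken in order of descending IOU; each ground
#' truth and each prediction is used at most once. Pairs with IOU below
#' `min_iou` are discarded (with `min_iou = 0`, any strictly positive
#' overlap matches). Leftover predictions are false positives,
#' leftover ground truths false negatives.
#'
#' @param gt,pred `BoundingBox` data.frames in the same ROI frame.
#' @param min_iou minimum IOU admitted as a match (default 0.001: the
#'   very-low-IOU false-positive rule).
#' @return object of class `MatchResult`: list(pairs (data.frame gt,
#'   pred, iou), fp (unmatched pred indices), fn (unmatched gt
#'   indices), min_iou).
#' @export
match_boxes <- function(gt, pred, min_iou = 0.001) {
  iou <- box_iou(gt, pred)
  pairs <- data.frame(gt = integer(0), pred = integer(0), iou = numeric(0))
  if (length(iou) > 0) {
    ord <- order(iou, decreasing = TRUE)
    gt_used <- rep(FALSE, nrow(gt)); pr_used <- rep(FALSE, nrow(pred))
    for (k in ord) {
      v <- iou[k]
      if (v < min_iou || v <= 0) break
      i <- (k - 1) %% nrow(iou) + 1
      j <- (k - 1) %/% nrow(iou) + 1
      if (gt_used[i] || pr_used[j]) next
      gt_used[i] <- TRUE; pr_used[j] <- TRUE
      pairs <- rbind(pairs, data.frame(gt = i, pred = j, iou = v))
    }
    fp <- which(!pr_used); fn <- which(!gt_used)
  } else {
    fp <- seq_len(nrow(pred)); fn <- seq_len(nrow(gt))
  }
  structure(list(pairs = pairs, fp = fp, fn = fn, min_iou = min_iou),
            class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult: %d matched, %d FP, %d FN (min IOU %g)\n",
              nrow(x$pairs), length(x$fp), length(x$fn), x$min_iou))
  invisible(x)
}

#' Object-level precision, recall and F1 from a match result
#'
#' @param match a `MatchResult`.
#' @return named list (precision, recall, f1, tp, fp, fn). A zero
#'   denominator yields 0 with a warning.
#' @export
object_prf <- function(match) {
  tp <- nrow(match$pairs); fp <- length(match$fp); fn <- length(match$fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else .zero_warn("object precision")
  recall <- if (tp + fn > 0) tp / (tp + fn) else .zero_warn("object recall")
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Non-maximum suppression
#'
#' Standard greedy NMS: boxes are visited in order of descending
#' confidence; a box is kept unless its IOU with an already kept box
#' exceeds `iou_thresh`.
#'
#' @param boxes `BoundingBox` data.frame with confidences.
#' @param iou_thresh suppression threshold.
#' @return the retained boxes.
#' @export
nms <- function(boxes, iou_thresh = 0.5) {
  if (nrow(boxes) == 0) return(boxes)
  if (any(is.na(boxes$confidence)))
    stop("NMS requires a confidence for every box")
  ord <- order(boxes$confidence, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) > 0 &&
        any(box_iou(boxes[i, , drop = FALSE],
                    boxes[keep, , drop = FALSE]) > iou_thresh)) next
    keep <- c(keep, i)
  }
  boxes[sort(keep), , drop = FALSE]
}

#' Average precision of a detector over one or more images
#'
#' All-point-interpolation AP at a fixed IOU threshold: predictions are
#' ranked by descending confidence across images; each is a true
#' positive if it matches a not-yet-claimed ground-truth box of its own
#' image at IOU >= `iou_thresh`. AP integrates the precision envelope
#' over recall.
#'
#' @param gt list of `BoundingBox` data.frames, one per image (or a
#'   single data.frame for one image).
#' @param pred matching list (or single data.frame) of predicted boxes
#'   with confidences.
#' @param iou_thresh match threshold (default 0.5, i.e. AP50).
#' @return list(ap, precision, recall) where precision/recall trace the
#'   PR staircase in rank order.
#' @export
average_precision <- function(gt, pred, iou_thresh = 0.5) {
  if (is.data.frame(gt)) gt <- list(gt)
  if (is.data.frame(pred)) pred <- list(pred)
  n_gt <- sum(vapply(gt, nrow, integer(1)))
  if (n_gt == 0) stop("average precision undefined: no ground-truth boxes")
  det <- do.call(rbind, lapply(seq_along(pred), function(im) {
    p <- pred[[im]]
    if (nrow(p) == 0) return(NULL)
    data.frame(im = im, idx = seq_len(nrow(p)), conf = p$confidence)
  }))
  if (is.null(det) || nrow(det) == 0)
    return(list(ap = 0, precision = numeric(0), recall = numeric(0)))
  if (any(is.na(det$conf))) stop("average precision requires confidences")
  det <- det[order(det$conf, decreasing = TRUE), , drop = FALSE]
  used <- lapply(gt, function(g) rep(FALSE, nrow(g)))
  tp <- logical(nrow(det))
  for (k in seq_len(nrow(det))) {
    im <- det$im[k]
    g <- gt[[im]]
    if (nrow(g) == 0) next
    iou <- box_iou(g, pred[[im]][det$idx[k], , drop = FALSE])[, 1]
    iou[used[[im]]] <- -1
    best <- which.max(iou)
    if (iou[best] >= iou_thresh) {
      tp[k] <- TRUE
      used[[im]][best] <- TRUE
    }
  }
  ctp <- cumsum(tp)
  precision <- ctp / seq_along(tp)
  recall <- ctp / n_gt
  # precision envelope (all-point interpolation)
  env <- rev(cummax(rev(precision)))
  rec_aug <- c(0, recall)
  ap <- sum((rec_aug[-1] - rec_aug[-length(rec_aug)]) * env)
  list(ap = ap, precision = precision, recall = recall)
}

#' Mean AP over IOU thresholds 0.50 to 0.95
#'
#' @inheritParams average_precision
#' @param thresholds IOU thresholds (default seq(0.5, 0.95, 0.05)).
#' @return mean AP across thresholds.
#' @export
average_precision_range <- function(gt, pred,
                                    thresholds = seq(0.5, 0.95, by = 0.05)) {
  mean(vapply(thresholds,
              function(t) average_precision(gt, pred, t)$ap, numeric(1)))
}

#' Assign boxes to grid tiles by centre containment
#'
#' Each box goes to the single tile whose half-open extent contains its
#' centre; coordinates are shifted into the tile frame and clipped to
#' the tile bounds. Boxes whose centre lies outside every tile are
#' dropped with a warning.
#'
#' @param boxes `BoundingBox` data.frame in the ROI frame.
#' @param grid a `TileIndex` from [build_tile_grid()].
#' @return named list of `BoundingBox` data.frames keyed
#'   `"x<j>_y<i>"` by tile origin; only non-empty tiles appear.
#' @export
assign_boxes_to_tiles <- function(boxes, grid) {
  out <- list()
  if (nrow(boxes) == 0) return(out)
  ctr <- .box_centers(boxes)
  dropped <- 0L
  for (k in seq_len(nrow(boxes))) {
    hit <- which(ctr[k, 1] >= grid$x & ctr[k, 1] < grid$x + grid$w &
                 ctr[k, 2] >= grid$y & ctr[k, 2] < grid$y + grid$h)
    if (length(hit) == 0) { dropped <- dropped + 1L; next }
    hit <- hit[1]
    key <- sprintf("x%d_y%d", as.integer(grid$x[hit]), as.integer(grid$y[hit]))
    b <- boxes[k, , drop = FALSE]
    b$xmin <- max(0, b$xmin - grid$x[hit]); b$xmax <- min(grid$w[hit], b$xmax - grid$x[hit])
    b$ymin <- max(0, b$ymin - grid$y[hit]); b$ymax <- min(grid$h[hit], b$ymax - grid$y[hit])
    out[[key]] <- if (is.null(out[[key]])) b else rbind(out[[key]], b)
  }
  if (dropped > 0)
    warning(sprintf("%d box(es) with centres outside the grid were dropped", dropped))
  out
}

#' Write or read detection text files
#'
#' One box per line: `label xmin ymin xmax ymax [confidence]`,
#' absolute pixel coordinates, whitespace-separated; the file basename
#' pairs with its tile image.
#'
#' @param boxes `BoundingBox` data.frame.
#' @param path text file path.
#' @param with_confidence append the confidence column when present.
#' @return the path (write) / a `BoundingBox` data.frame (read).
#' @export
write_detections <- function(boxes, path, with_confidence = FALSE) {
  cols <- c("label", "xmin", "ymin", "xmax", "ymax")
  if (with_confidence) cols <- c(cols, "confidence")
  df <- as.data.frame(boxes)[, cols, drop = FALSE]
  txt <- lapply(df, function(v)
    vapply(v, function(x) format(x, trim = TRUE, scientific = FALSE),
           character(1)))
  writeLines(do.call(paste, c(txt, sep = " ")), path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(.empty_boxes())
  fields <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 5)) stop("detection lines need at least 5 fields")
  m <- do.call(rbind, lapply(fields, function(f) f[1:5]))
  conf <- vapply(fields, function(f) if (length(f) >= 6) f[6] else NA_real_,
                 numeric(1))
  bounding_boxes(m[, 2], m[, 3], m[, 4], m[, 5], confidence = conf,
                 label = as.integer(m[, 1]))
}
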