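#' Classical stain-threshold tile predictor
#'
#' Builds a predictor honouring the pluggable predictor contract
#' (tile RGB in, probability map of identical dims out) from the
#' DAB-binarization pipeline: per-tile colour deconvolution, Otsu
#' threshold and morphological cleaning, returned as hard 0/1
#' probabilities. Ships as the default prediction backend.
#'
#' @param morph_radius disk radius for the morphology, px.
#' @return function of class `nft_predictor`.
#' @export
predictor_classical <- function(morph_radius = 3) {
  f <- function(tile) {
    dm <- withCallingHandlers(
      dab_binary_mask(tile, morph_radius = morph_radius),
      warning = function(w) {
        if (grepl("degenerate", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    dm$mask * 1
  }
  structure(f, class = c("nft_predictor", "function"),
            name = "classical-dab-threshold")
}

#' Sliding-window whole-slide segmentation
#'
#' Predicts non-overlapping tiles independently (stride equal to tile
#' size, matching inference practice), thresholds each probability map
#' and places it at its coordinates. Border tiles are padded to the
#' predictor's tile size with white and clipped back on placement.
#'
#' @param wsi H x W x 3 RGB array (or `ChunkedStore`).
#' @param predictor an `nft_predictor` (default
#'   [predictor_classical()]).
#' @param tile tile edge, px.
#' @param stride must equal `tile`.
#' @param threshold probability cut (inclusive).
#' @return logical H x W mask.
#' @export
sliding_window_segment <- function(wsi, predictor = predictor_classical(),
                                   tile = 1024, stride = tile,
                                   threshold = 0.5) {
  if (stride != tile)
    stop("sliding-window inference uses stride equal to tile size")
  from_store <- inherits(wsi, "ChunkedStore")
  d <- if (from_store) c(wsi$dims, 3L) else dim(wsi)
  if (!from_store) .check_rgb(wsi)
  out <- matrix(FALSE, d[1], d[2])
  for (y0 in seq(0, d[1] - 1, by = stride)) {
    for (x0 in seq(0, d[2] - 1, by = stride)) {
      w <- min(tile, d[2] - x0); h <- min(tile, d[1] - y0)
      blk <- if (from_store) read_chunked(wsi, x0, y0, w, h)
             else wsi[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), , drop = FALSE]
      if (w < tile || h < tile) {
        padded <- array(255L, c(tile, tile, 3L))
        padded[1:h, 1:w, ] <- blk
        blk <- padded
      }
      prob <- predictor(blk)
      if (!all(dim(prob) == c(tile, tile)))
        stop("predictor output dims do not match its input tile")
      out[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)] <-
        binarize(prob, threshold)[1:h, 1:w]
    }
  }
  out
}

#' Block-reduce a matrix by max or mean
#'
#' Pads to a multiple of `factor` (zeros) and reduces each
#' factor x factor block. Max reduction keeps thin detections alive
#' through coarse downscaling.
#'
#' @param m numeric/logical matrix.
#' @param factor block edge (>= 1).
#' @param op "max" or "mean".
#' @return reduced matrix of dims ceiling(dim(m) / factor).
#' @export
block_reduce <- function(m, factor = 64, op = c("max", "mean")) {
  op <- match.arg(op)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(m * 1)
  H <- nrow(m); W <- ncol(m)
  Hp <- ceiling(H / factor) * factor; Wp <- ceiling(W / factor) * factor
  mp <- matrix(0, Hp, Wp)
  mp[1:H, 1:W] <- m
  # block sums via banded indicator matrices (fast, no loops)
  A <- matrix(0, Hp / factor, Hp)
  A[cbind(rep(seq_len(Hp / factor), each = factor), seq_len(Hp))] <- 1
  B <- matrix(0, Wp, Wp / factor)
  B[cbind(seq_len(Wp), rep(seq_len(Wp / factor), each = factor))] <- 1
  if (op == "mean") return((A %*% mp %*% B) / factor^2)
  if (all(mp %in% c(0, 1))) return(((A %*% mp %*% B) > 0) * 1)
  # generic max for non-binary input
  red <- matrix(-Inf, Hp / factor, Wp / factor)
  for (i in seq_len(factor)) for (j in seq_len(factor)) {
    sub <- mp[seq(i, Hp, by = factor), seq(j, Wp, by = factor), drop = FALSE]
    red <- pmax(red, sub)
  }
  red
}

#' Count detection blobs at reduced resolution
#'
#' Block-max reduces the WSI mask by `factor` and counts 8-connected
#' components. Blobs closer than about one reduced pixel can fuse; the
#' reduction trades that for tractable whole-slide counting.
#'
#' @param mask logical WSI mask.
#' @param factor downscale factor (default 64).
#' @param connectivity component connectivity after reduction.
#' @return integer blob count.
#' @export
count_blobs_downscaled <- function(mask, factor = 64, connectivity = 8) {
  red <- block_reduce(mask > 0, factor, "max")
  max(label_components(red > 0, connectivity))
}

#' Tissue mask and area of a slide image
#'
#' Downscales by block mean, converts to grayscale optical density,
#' separates tissue from white background by Otsu threshold and closes
#' small holes. An all-white (empty) slide yields zero area.
#'
#' @param wsi H x W x 3 RGB array.
#' @param factor downscale factor (default 64).
#' @param hole_radius closing radius (reduced px) for hole filling.
#' @return list(mask (logical, reduced dims), area (foreground px at
#'   reduced resolution), factor).
#' @export
tissue_mask <- function(wsi, factor = 64, hole_radius = 2) {
  .check_rgb(wsi)
  gray <- (block_reduce(wsi[, , 1], factor, "mean") +
           block_reduce(wsi[, , 2], factor, "mean") +
           block_reduce(wsi[, , 3], factor, "mean")) / 3
  od <- -log10(pmax(gray, 1) / 255)
  if (diff(range(od)) < 1e-6)
    return(list(mask = matrix(FALSE, nrow(od), ncol(od)), area = 0L,
                factor = factor))
  thr <- EBImage::otsu(od / max(od), range = c(0, 1), levels = 256) * max(od)
  m <- od >= thr
  if (hole_radius > 0) {
    kern <- EBImage::makeBrush(2 * hole_radius + 1, shape = "disc")
    m <- as.matrix(EBImage::closing(m * 1, kern)) > 0.5
    m <- as.matrix(EBImage::fillHull(m * 1)) > 0.5
  }
  list(mask = m, area = sum(m), factor = factor)
}

#' NFT burden score of a slide
#'
#' Blob count normalised by tissue area and rescaled by the cohort's
#' median tissue area so scores are comparable across slides:
#' score = count / tissue_area * median_area. A slide with zero
#' detections scores exactly 0.
#'
#' @param count blob count (downscaled resolution).
#' @param tissue_area tissue area in downscaled px (> 0).
#' @param median_area median training-set tissue area, same units.
#' @return scalar score.
#' @export
nft_detector_score <- function(count, tissue_area, median_area) {
  if (tissue_area <= 0) stop("tissue area must be > 0")
  count / tissue_area * median_area
}

#' Annotator-analog burden score
#'
#' The same functional form as [nft_detector_score()] with the number
#' of human point annotations in place of the detected blob count and
#' the total annotated ROI pixel area as the normaliser. Optional
#' min-max normalisation aligns axes for plotting only.
#'
#' @param n_points point-annotation count across the slide's ROIs.
#' @param roi_area total ROI pixel area (> 0).
#' @param median_area rescale constant (same units as roi_area).
#' @return scalar score.
#' @export
annotator_score <- function(n_points, roi_area, median_area) {
  if (roi_area <= 0) stop("ROI area must be > 0")
  n_points / roi_area * median_area
}

#' Score a slide end to end
#'
#' Runs [sliding_window_segment()], [count_blobs_downscaled()] and
#' [tissue_mask()] and combines them into an [nft_detector_score()].
#'
#' @param wsi H x W x 3 RGB array.
#' @param predictor prediction backend.
#' @param tile inference tile size, px.
#' @param factor downscale factor for counting and tissue area.
#' @param median_area rescale constant (defaults to this slide's own
#'   tissue area, giving score = count).
#' @param wsi_id identifier.
#' @return object of class `SlideScore`: list(wsi_id, count,
#'   tissue_area, median_area, score, source).
#' @export
score_slide <- function(wsi, predictor = predictor_classical(), tile = 1024,
                        factor = 64, median_area = NULL, wsi_id = "wsi") {
  seg <- sliding_window_segment(wsi, predictor, tile = tile)
  count <- count_blobs_downscaled(seg, factor)
  tis <- tissue_mask(wsi, factor)
  if (is.null(median_area)) median_area <- tis$area
  structure(
    list(wsi_id = wsi_id, count = count, tissue_area = tis$area,
         median_area = median_area,
         score = nft_detector_score(count, tis$area, median_area),
         source = "model"),
    class = "SlideScore")
}

#' @export
print.SlideScore <- function(x, ...) {
  cat(sprintf("SlideScore [%s]: %d blob(s), tissue %d px, score %.4f (%s)\n",
              x$wsi_id, x$count, x$tissue_area, x$score, x$source))
  invisible(x)
}

.grade_levels <- c("none", "sparse", "moderate", "frequent")

#' Rank correlation of burden scores with ordinal slide grades
#'
#' Spearman's rho (midrank ties) between slide scores and
#' CERAD-like ordinal grades coded 0-3
#' (none/sparse/moderate/frequent).
#'
#' @param scores numeric slide scores.
#' @param grades integer codes 0-3, or a factor/character over the
#'   grade levels.
#' @return list(rho, p): rho is the Pearson correlation of midranks
#'   (the standard tie-corrected Spearman estimate), p the two-sided
#'   t-approximation p value.
#' @export
correlate_with_grades <- function(scores, grades) {
  g <- .code_grades(grades)
  n <- length(scores)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(g)) < 2)
    stop("Spearman correlation undefined for constant grades")
  rho <- stats::cor(rank(scores), rank(g))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p)
}

.code_grades <- function(grades) {
  if (is.numeric(grades)) {
    if (any(!grades %in% 0:3)) stop("numeric grades must be coded 0-3")
    return(as.numeric(grades))
  }
  g <- match(tolower(as.character(grades)), .grade_levels) - 1
  if (any(is.na(g))) stop("grades must be one of: ",
                          paste(.grade_levels, collapse = ", "))
  as.numeric(g)
}

#' Welch comparisons between adjacent grade groups
#'
#' Unequal-variance (Welch) t statistic and two-sided p value for each
#' adjacent pair of ordinal grade groups. Groups with fewer than two
#' observations are skipped with a warning. When both groups have zero
#' variance the pair is flagged degenerate: identical groups give
#' t = 0, p = 1; differing means give p -> 0.
#'
#' @param scores numeric slide scores.
#' @param grades ordinal grades (see [correlate_with_grades()]).
#' @return data.frame (group1, group2, n1, n2, t, df, p, degenerate).
#' @export
compare_grade_groups <- function(scores, grades) {
  g <- .code_grades(grades)
  lev <- sort(unique(g))
  res <- list()
  for (k in seq_len(length(lev) - 1)) {
    a <- scores[g == lev[k]]; b <- scores[g == lev[k + 1]]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("pair %d-%d skipped: singleton group", lev[k], lev[k + 1]))
      next
    }
    va <- stats::var(a); vb <- stats::var(b)
    se2 <- va / length(a) + vb / length(b)
    degen <- se2 == 0
    if (degen) {
      tt <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
      df <- NA_real_
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tt <- (mean(a) - mean(b)) / sqrt(se2)
      df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                     (vb / length(b))^2 / (length(b) - 1))
      p <- 2 * stats::pt(-abs(tt), df)
    }
    res[[length(res) + 1L]] <- data.frame(
      group1 = lev[k], group2 = lev[k + 1],
      n1 = length(a), n2 = length(b),
      t = tt, df = df, p = p, degenerate = degen)
  }
  if (length(res) == 0)
    return(data.frame(group1 = numeric(0), group2 = numeric(0),
                      n1 = integer(0), n2 = integer(0), t = numeric(0),
                      df = numeric(0), p = numeric(0), degenerate = logical(0)))
  do.call(rbind, res)
}
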