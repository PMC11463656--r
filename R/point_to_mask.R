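#' Crop a tile centred on a point annotation
#'
#' Extracts a `size` x `size` RGB crop centred on the annotated
#' nucleolus. Regions falling outside the ROI are padded with constant
#' white (255), so padded pixels never enter the DAB mask. The point
#' maps to the crop centre (size/2, size/2).
#'
#' @param roi H x W x 3 RGB array.
#' @param point length-2 numeric (x, y) or one-row data.frame with
#'   columns `x`, `y` (0-based ROI coordinates).
#' @param size tile edge in px (default 400).
#' @param id annotation identifier carried through the pipeline.
#' @return object of class `TileCrop`: list(rgb, id, origin, pad) where
#'   `origin` is the crop's (x, y) position in the ROI frame (may be
#'   negative) and `pad` gives left/right/top/bottom pad widths.
#' @export
crop_tile <- function(roi, point, size = 400, id = NA) {
  .check_rgb(roi)
  if (is.data.frame(point)) point <- c(point$x[1], point$y[1])
  d <- dim(roi)
  x <- round(point[1]); y <- round(point[2])
  if (x < 0 || x >= d[2] || y < 0 || y >= d[1])
    stop(sprintf("point (%d, %d) lies outside the %d x %d ROI", x, y, d[2], d[1]))
  half <- size %/% 2
  x0 <- x - half; y0 <- y - half
  xs <- x0:(x0 + size - 1); ys <- y0:(y0 + size - 1)
  inx <- xs >= 0 & xs < d[2]; iny <- ys >= 0 & ys < d[1]
  crop <- array(255L, c(size, size, 3L))
  crop[which(iny), which(inx), ] <- roi[ys[iny] + 1, xs[inx] + 1, , drop = FALSE]
  pad <- c(left = sum(!inx & xs < 0), right = sum(!inx & xs >= d[2]),
           top = sum(!iny & ys < 0), bottom = sum(!iny & ys >= d[1]))
  structure(list(rgb = crop, id = id, origin = c(x = x0, y = y0), pad = pad),
            class = "TileCrop")
}

#' Centre-biased blob selection
#'
#' The filter that turns a binarized DAB tile into the mask of its
#' annotated tangle: (i) label connected components, (ii) remove
#' components whose centre of mass lies more than `center_bias` px from
#' the tile centre, (iii) find the largest surviving component,
#' (iv) remove survivors whose area is strictly below `size_frac` times
#' the largest area. Both rule boundaries are inclusive for retention:
#' a centroid at exactly `center_bias` px stays, and an area of exactly
#' `size_frac * largest` stays.
#'
#' @param bw logical (or 0/1) square matrix, typically 400 x 400.
#' @param center_bias maximum centroid distance from the tile centre,
#'   px. Default 120 (the corrected value; the legacy value 80 missed
#'   ~7% of tiles with long-tailed tangles).
#' @param size_frac minimum area as a fraction of the largest retained
#'   blob.
#' @param connectivity component connectivity (8 or 4).
#' @param id annotation identifier.
#' @return object of class `TileMask`: list(mask, id, retained
#'   (component count), largest_area).
#' @export
select_center_blobs <- function(bw, center_bias = 120, size_frac = 0.5,
                                connectivity = 8, id = NA) {
  if (!is.matrix(bw)) stop("bw must be a matrix")
  bw <- bw > 0
  d <- dim(bw)
  ctr <- c(d[2] / 2, d[1] / 2)          # (x, y), 0-based
  lab <- label_components(bw, connectivity)
  n <- max(lab)
  empty <- structure(list(mask = matrix(FALSE, d[1], d[2]), id = id,
                          retained = 0L, largest_area = 0L),
                     class = "TileMask")
  if (n == 0) return(empty)
  idx <- which(lab > 0)
  lv <- lab[idx]
  rows <- ((idx - 1) %% d[1])           # 0-based row = y
  cols <- ((idx - 1) %/% d[1])          # 0-based col = x
  cy <- tapply(rows, lv, mean); cx <- tapply(cols, lv, mean)
  area <- tabulate(lv, n)
  dist <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2)
  keep <- which(dist <= center_bias)
  if (length(keep) == 0) return(empty)
  largest <- max(area[keep])
  keep <- keep[area[keep] >= size_frac * largest]
  mask <- matrix(FALSE, d[1], d[2])
  mask[idx[lv %in% keep]] <- TRUE
  structure(list(mask = mask, id = id, retained = length(keep),
                 largest_area = as.integer(largest)),
            class = "TileMask")
}

#' @export
print.TileMask <- function(x, ...) {
  cat(sprintf("TileMask [%s]: %d blob(s) retained, largest %d px\n",
              as.character(x$id), x$retained, x$largest_area))
  invisible(x)
}

#' Convert one point annotation to a tile mask
#'
#' The bootstrapping pipeline for a single annotation: crop a tile
#' around the point ([crop_tile()]), binarize its DAB channel
#' ([dab_binary_mask()]) and select the centre-biased blobs
#' ([select_center_blobs()]). An empty result (point on blank tissue)
#' is valid and flagged via `retained == 0`.
#'
#' @inheritParams crop_tile
#' @inheritParams select_center_blobs
#' @param morph_radius disk radius for the DAB-mask morphology, px.
#' @return a `TileMask` with the crop `origin` and `pad` attached.
#' @export
point_to_mask <- function(roi, point, size = 400, center_bias = 120,
                          size_frac = 0.5, morph_radius = 3,
                          connectivity = 8, id = NA) {
  crop <- crop_tile(roi, point, size = size, id = id)
  dm <- withCallingHandlers(
    dab_binary_mask(crop$rgb, morph_radius = morph_radius),
    warning = function(w) {
      if (grepl("degenerate", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  tm <- select_center_blobs(dm$mask, center_bias = center_bias,
                            size_frac = size_frac,
                            connectivity = connectivity, id = id)
  tm$origin <- crop$origin
  tm$pad <- crop$pad
  tm
}

#' Run the point-to-mask pipeline over all annotations of an ROI
#'
#' @param roi H x W x 3 RGB array.
#' @param points data.frame with columns `x`, `y` (0-based).
#' @param ... passed to [point_to_mask()].
#' @return list of `TileMask` objects (ids = row numbers unless the
#'   points table has an `id` column).
#' @export
points_to_masks <- function(roi, points, ...) {
  ids <- if (!is.null(points$id)) points$id else seq_len(nrow(points))
  lapply(seq_len(nrow(points)), function(i)
    point_to_mask(roi, c(points$x[i], points$y[i]), id = ids[i], ...))
}

#' Stitch tile masks into an ROI-level ground-truth mask
#'
#' Pixel-wise union (OR) of the tile masks placed at their crop
#' origins; portions outside the ROI (padding) are clipped away.
#' Stitching is order-independent.
#'
#' @param dims length-2 (H, W) of the ROI.
#' @param tiles list of `TileMask` objects carrying an `origin`
#'   element, or a list of `list(mask =, origin = c(x, y))`.
#' @param version annotation version recorded on the result.
#' @return object of class `ROIMask`: list(mask (logical H x W), ids,
#'   version).
#' @export
stitch_masks <- function(dims, tiles, version = 1L) {
  H <- dims[1]; W <- dims[2]
  out <- matrix(FALSE, H, W)
  ids <- c()
  for (tm in tiles) {
    m <- tm$mask; org <- tm$origin
    if (is.null(org)) stop("tile mask lacks a crop origin")
    td <- dim(m)
    x0 <- org[1]; y0 <- org[2]
    if (x0 + td[2] <= 0 || x0 >= W || y0 + td[1] <= 0 || y0 >= H)
      stop("tile origin places the mask fully outside the ROI")
    xs <- max(0, x0):min(W - 1, x0 + td[2] - 1)
    ys <- max(0, y0):min(H - 1, y0 + td[1] - 1)
    out[ys + 1, xs + 1] <- out[ys + 1, xs + 1] |
      m[ys - y0 + 1, xs - x0 + 1, drop = FALSE]
    ids <- c(ids, tm$id)
  }
  structure(list(mask = out, ids = ids, version = as.integer(version)),
            class = "ROIMask")
}

#' Tile-mask size QC report
#'
#' Tabulates each bootstrapped mask's area and its fraction of the
#' tile, and counts empty masks and over-size outliers. Over-segmented
#' outliers are retained, not hand-fixed; this report is how they
#' surface.
#'
#' @param tiles list of `TileMask` objects.
#' @param tile_px tile edge in px (fraction denominator is tile_px^2).
#' @param oversize_frac fraction above which a mask is flagged as an
#'   over-segmentation outlier.
#' @return data.frame (id, area, fraction, empty, oversize) with
#'   attributes `n_empty` and `n_oversize`.
#' @export
mask_size_report <- function(tiles, tile_px = 400, oversize_frac = 0.32) {
  area <- vapply(tiles, function(t) sum(t$mask), numeric(1))
  ids <- vapply(tiles, function(t) as.character(t$id), character(1))
  frac <- area / tile_px^2
  out <- data.frame(id = ids, area = area, fraction = frac,
                    empty = area == 0, oversize = frac > oversize_frac,
                    stringsAsFactors = FALSE)
  attr(out, "n_empty") <- sum(out$empty)
  attr(out, "n_oversize") <- sum(out$oversize)
  out
}
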