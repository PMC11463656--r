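#' Slice an ROI into review super-tiles
#'
#' Divides the ROI into round(W / tile_w) columns by round(H / tile_h)
#' rows of large review crops; the final row/column is resized to reach
#' the ROI edge so every ROI pixel belongs to exactly one frame. An ROI
#' at the reference dimensions 21,236 x 10,680 px slices into 5 x 3 =
#' 15 super-tiles of nominally 4247 x 3560 px. Display order for
#' export can be randomised with a seed.
#'
#' @param dims length-2 (H, W) of the ROI.
#' @param tile_w,tile_h nominal super-tile width and height, px.
#' @param roi_id identifier recorded per frame.
#' @param seed optional seed randomising `display_id`.
#' @return data.frame of class `SuperTileFrames` with columns roi_id,
#'   row, col, x, y, w, h, tile_id, display_id.
#' @export
slice_super_tiles <- function(dims, tile_w = 4247, tile_h = 3560,
                              roi_id = "roi", seed = NULL) {
  H <- dims[1]; W <- dims[2]
  if (W < tile_w || H < tile_h)
    warning("ROI smaller than one super-tile: returning a single clipped tile")
  nc <- max(1L, as.integer(round(W / tile_w)))
  nr <- max(1L, as.integer(round(H / tile_h)))
  grid <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  grid$x <- grid$col * tile_w
  grid$y <- grid$row * tile_h
  grid$w <- ifelse(grid$col == nc - 1L, W - grid$x, tile_w)
  grid$h <- ifelse(grid$row == nr - 1L, H - grid$y, tile_h)
  grid$w <- pmin(grid$w, W - grid$x)
  grid$h <- pmin(grid$h, H - grid$y)
  grid$tile_id <- sprintf("%s_r%d_c%d", roi_id, grid$row, grid$col)
  ord <- seq_len(nrow(grid))
  if (!is.null(seed)) { set.seed(seed); ord <- sample(ord) }
  grid$display_id <- sprintf("st_%04d", order(ord))
  out <- data.frame(roi_id = roi_id,
                    grid[, c("row", "col", "x", "y", "w", "h",
                             "tile_id", "display_id")],
                    stringsAsFactors = FALSE)
  class(out) <- c("SuperTileFrames", class(out))
  out
}

#' Compose a side-by-side re-annotation review image
#'
#' Left panel: the super-tile blended with its agreement-map overlay
#' (TP cyan, FP yellow, FN magenta); right panel: the raw super-tile.
#' Output width is twice the tile width.
#'
#' @param tile H x W x 3 RGB array.
#' @param am `AgreementMap` with matching dims.
#' @param alpha overlay blend weight.
#' @return H x 2W x 3 integer array.
#' @export
compose_review_image <- function(tile, am, alpha = 0.5) {
  .check_rgb(tile)
  if (!all(dim(tile)[1:2] == dim(am$map)))
    stop("agreement map dims do not match the super-tile")
  left <- render_agreement_overlay(tile, am, alpha)
  d <- dim(tile)
  out <- array(0L, c(d[1], 2L * d[2], 3L))
  out[, 1:d[2], ] <- left
  out[, (d[2] + 1):(2 * d[2]), ] <- tile
  storage.mode(out) <- "integer"
  out
}

#' Ingest re-annotation points back into the ROI frame
#'
#' Converts point records made on super-tile review images into
#' ROI-frame annotations (tile offset + local coordinates), tagged
#' version 2, and merges them with the existing version-1 points
#' without deleting anything (additive-only contract). Records whose
#' image id resolves to no registered frame are quarantined, not
#' silently dropped.
#'
#' @param records data.frame with columns `image_id` (matching
#'   `tile_id` or `display_id` in the registry), `x`, `y` (super-tile
#'   local, 0-based).
#' @param registry `SuperTileFrames` from [slice_super_tiles()].
#' @param existing optional version-1 `PointAnnotation` data.frame to
#'   merge with.
#' @param annotator tag recorded on the new points.
#' @return `PointAnnotation` data.frame (existing rows first, then the
#'   new version-2 rows) with attribute `quarantined` holding
#'   unresolvable records.
#' @export
ingest_new_points <- function(records, registry, existing = NULL,
                              annotator = "expert") {
  newpts <- list(); quarantined <- records[0, , drop = FALSE]
  for (i in seq_len(nrow(records))) {
    hit <- which(registry$tile_id == records$image_id[i] |
                 registry$display_id == records$image_id[i])
    if (length(hit) == 0) {
      quarantined <- rbind(quarantined, records[i, , drop = FALSE])
      next
    }
    hit <- hit[1]
    newpts[[length(newpts) + 1L]] <- data.frame(
      roi_id = registry$roi_id[hit],
      x = registry$x[hit] + records$x[i],
      y = registry$y[hit] + records$y[i],
      version = 2L, annotator = annotator, stringsAsFactors = FALSE)
  }
  if (nrow(quarantined) > 0)
    warning(sprintf("%d record(s) quarantined: unresolvable image id",
                    nrow(quarantined)))
  new_df <- if (length(newpts)) do.call(rbind, newpts) else
    data.frame(roi_id = character(0), x = numeric(0), y = numeric(0),
               version = integer(0), annotator = character(0),
               stringsAsFactors = FALSE)
  out <- if (!is.null(existing)) rbind(as.data.frame(existing), new_df)
         else new_df
  class(out) <- c("PointAnnotation", "data.frame")
  attr(out, "quarantined") <- quarantined
  out
}

#' Map ROI-frame points into their super-tile frames
#'
#' Inverse of the ingest offset: locates each point's super-tile and
#' subtracts the frame offset. Round trip ROI -> super-tile -> ROI via
#' [ingest_new_points()] is the identity.
#'
#' @param points data.frame with `x`, `y` (ROI frame).
#' @param registry `SuperTileFrames`.
#' @return data.frame (image_id, x, y) in super-tile-local coordinates.
#' @export
points_to_super_tiles <- function(points, registry) {
  out <- list()
  for (i in seq_len(nrow(points))) {
    hit <- which(points$x[i] >= registry$x & points$x[i] < registry$x + registry$w &
                 points$y[i] >= registry$y & points$y[i] < registry$y + registry$h)
    if (length(hit) == 0) next
    hit <- hit[1]
    out[[length(out) + 1L]] <- data.frame(
      image_id = registry$tile_id[hit],
      x = points$x[i] - registry$x[hit],
      y = points$y[i] - registry$y[hit], stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(image_id = character(0), x = numeric(0), y = numeric(0)))
  do.call(rbind, out)
}
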