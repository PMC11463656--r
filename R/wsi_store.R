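#' Write an RGB image to a chunked on-disk store
#'
#' Stores an 8-bit RGB array as a directory of losslessly compressed
#' per-chunk PNG files plus a JSON sidecar. The contract is byte
#' identity on round trip; the default chunk edge of 5000 px matches
#' whole-slide processing practice (border chunks are smaller).
#'
#' @param image H x W x 3 array, values 0..255.
#' @param path directory to create.
#' @param chunk chunk edge length in px.
#' @return object of class `ChunkedStore`: list(path, dims, chunk).
#' @export
store_chunked <- function(image, path, chunk = 5000) {
  .check_rgb(image)
  if (chunk < 1) stop("chunk must be >= 1")
  d <- dim(image)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nr <- ceiling(d[1] / chunk); nc <- ceiling(d[2] / chunk)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    rows <- ((r - 1) * chunk + 1):min(r * chunk, d[1])
    cols <- ((cc - 1) * chunk + 1):min(cc * chunk, d[2])
    blk <- image[rows, cols, , drop = FALSE] / 255
    png::writePNG(blk, file.path(path, sprintf("c_%04d_%04d.png", r - 1, cc - 1)))
  }
  meta <- list(height = d[1], width = d[2], channels = 3L,
               chunk = as.integer(chunk), codec = "png")
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  structure(list(path = path, dims = d[1:2], chunk = as.integer(chunk)),
            class = "ChunkedStore")
}

#' Open an existing chunked store
#' @param path store directory.
#' @return a `ChunkedStore` reference.
#' @export
open_chunked <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  structure(list(path = path, dims = c(meta$height, meta$width),
                 chunk = as.integer(meta$chunk)),
            class = "ChunkedStore")
}

#' Number of chunks in a store
#' @param store a `ChunkedStore`.
#' @return length-2 integer (rows, cols) of the chunk grid.
#' @export
chunk_grid <- function(store) {
  as.integer(ceiling(store$dims / store$chunk))
}

#' Read a full image or a region from a chunked store
#'
#' @param store a `ChunkedStore` (or store path).
#' @param x,y,w,h optional region (0-based origin, px); full image when
#'   omitted.
#' @return H x W x 3 integer array, values 0..255.
#' @export
read_chunked <- function(store, x = 0, y = 0, w = NULL, h = NULL) {
  if (is.character(store)) store <- open_chunked(store)
  H <- store$dims[1]; W <- store$dims[2]; ck <- store$chunk
  if (is.null(w)) w <- W - x
  if (is.null(h)) h <- H - y
  if (x < 0 || y < 0 || x + w > W || y + h > H)
    stop("requested region outside stored image")
  out <- array(0L, c(h, w, 3L))
  r_lo <- floor(y / ck); r_hi <- floor((y + h - 1) / ck)
  c_lo <- floor(x / ck); c_hi <- floor((x + w - 1) / ck)
  for (r in r_lo:r_hi) for (cc in c_lo:c_hi) {
    f <- file.path(store$path, sprintf("c_%04d_%04d.png", r, cc))
    blk <- png::readPNG(f)
    if (length(dim(blk)) == 2) blk <- array(blk, c(dim(blk), 1L))[, , c(1, 1, 1)]
    blk <- round(blk[, , 1:3, drop = FALSE] * 255)
    storage.mode(blk) <- "integer"
    gy0 <- r * ck; gx0 <- cc * ck
    ys <- max(y, gy0):min(y + h - 1, gy0 + dim(blk)[1] - 1)
    xs <- max(x, gx0):min(x + w - 1, gx0 + dim(blk)[2] - 1)
    out[ys - y + 1, xs - x + 1, ] <- blk[ys - gy0 + 1, xs - gx0 + 1, ]
  }
  out
}

# rotation frame helpers -------------------------------------------------

# corners: 4 x 2 matrix (x, y), clockwise from top-left, half-open
# convention (an axis-aligned w x h rectangle at origin has corners
# (0,0), (w,0), (w,h), (0,h)).
.roi_frame <- function(corners) {
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(4, 2))) stop("corners must be a 4 x 2 matrix")
  ex <- corners[2, ] - corners[1, ]
  ey <- corners[4, ] - corners[1, ]
  wlen <- sqrt(sum(ex^2)); hlen <- sqrt(sum(ey^2))
  angle <- atan2(ex[2], ex[1])
  u <- ex / wlen; v <- ey / hlen
  if (abs(sum(u * v)) > 0.01)
    stop("corners do not form a rectangle (adjacent edges not perpendicular)")
  list(origin = corners[1, ], u = u, v = v, angle = angle,
       w = round(wlen), h = round(hlen))
}

#' Describe a (possibly rotated) annotated region of a WSI
#'
#' @param corners 4 x 2 matrix of (x, y) WSI pixel coordinates,
#'   clockwise from the top-left corner.
#' @param roi_id,wsi_id identifiers.
#' @return object of class `ROIRecord` with the rotation angle
#'   (radians) and extracted dims (H, W) derived from the corners.
#' @export
roi_record <- function(corners, roi_id = "roi", wsi_id = "wsi") {
  fr <- .roi_frame(corners)
  structure(
    list(roi_id = roi_id, wsi_id = wsi_id, corners = as.matrix(corners),
         angle = fr$angle, dims = c(fr$h, fr$w)),
    class = "ROIRecord")
}

#' Extract a rotated rectangular ROI from a WSI image
#'
#' Samples the axis-alignable ROI content by an inverse-mapped bilinear
#' warp: each output pixel centre is mapped through the rectangle's
#' rotation frame into the source image and interpolated. Angles that
#' are exact multiples of 90 degrees land on integer source indices, so
#' those extractions are exact (no interpolation error).
#'
#' @param wsi H x W x 3 array (or `ChunkedStore`).
#' @param corners 4 x 2 corner matrix, clockwise from top-left
#'   (half-open: an unrotated w x h ROI at (x0, y0) has corners
#'   (x0, y0), (x0+w, y0), (x0+w, y0+h), (x0, y0+h)).
#' @param roi_id,wsi_id identifiers for the returned record.
#' @return list(image = extracted H x W x 3 array, record = [roi_record()]).
#' @export
extract_rotated_roi <- function(wsi, corners, roi_id = "roi", wsi_id = "wsi") {
  if (inherits(wsi, "ChunkedStore")) wsi <- read_chunked(wsi)
  .check_rgb(wsi)
  d <- dim(wsi)
  corners <- as.matrix(corners)
  for (k in 1:4) {
    if (corners[k, 1] < 0 || corners[k, 1] > d[2] ||
        corners[k, 2] < 0 || corners[k, 2] > d[1])
      stop(sprintf("corner %d (%.1f, %.1f) lies outside the %d x %d image",
                   k, corners[k, 1], corners[k, 2], d[2], d[1]))
  }
  fr <- .roi_frame(corners)
  rec <- roi_record(corners, roi_id, wsi_id)
  W <- fr$w; H <- fr$h
  xl <- rep(0:(W - 1), each = H)
  yl <- rep(0:(H - 1), W)
  # pixel-centre mapping: source index = origin + (local + 0.5) * frame - 0.5
  sx <- fr$origin[1] + (xl + 0.5) * fr$u[1] + (yl + 0.5) * fr$v[1] - 0.5
  sy <- fr$origin[2] + (xl + 0.5) * fr$u[2] + (yl + 0.5) * fr$v[2] - 0.5
  out <- array(0, c(H, W, 3L))
  x0 <- pmin(pmax(floor(sx), 0), d[2] - 1); fx <- pmin(pmax(sx - x0, 0), 1)
  y0 <- pmin(pmax(floor(sy), 0), d[1] - 1); fy <- pmin(pmax(sy - y0, 0), 1)
  x1 <- pmin(x0 + 1, d[2] - 1); y1 <- pmin(y0 + 1, d[1] - 1)
  for (ch in 1:3) {
    pl <- wsi[, , ch]
    v00 <- pl[cbind(y0 + 1, x0 + 1)]; v01 <- pl[cbind(y0 + 1, x1 + 1)]
    v10 <- pl[cbind(y1 + 1, x0 + 1)]; v11 <- pl[cbind(y1 + 1, x1 + 1)]
    out[, , ch] <- matrix((1 - fy) * ((1 - fx) * v00 + fx * v01) +
                          fy * ((1 - fx) * v10 + fx * v11), H, W)
  }
  out <- round(pmin(pmax(out, 0), 255))
  storage.mode(out) <- "integer"
  list(image = out, record = rec)
}

#' Transform WSI-frame points into ROI-local coordinates
#'
#' Applies the inverse of the [extract_rotated_roi()] transform, so a
#' transformed point indexes the same tissue in the extracted image as
#' the original point did in the WSI (within 1 px for interpolated
#' angles).
#'
#' @param points data.frame with columns `x`, `y` (WSI pixel coords).
#' @param record an `ROIRecord`.
#' @param drop_outside drop points falling outside the ROI (default
#'   FALSE: they are kept and reported via the `outside` attribute and
#'   a warning).
#' @param version,annotator annotation metadata for the output table.
#' @return data.frame of class `PointAnnotation` with columns roi_id,
#'   x, y, version, annotator; attribute `outside` holds the row
#'   indices (in the input) of out-of-ROI points.
#' @export
points_global_to_local <- function(points, record, drop_outside = FALSE,
                                   version = 1L, annotator = "annotator") {
  fr <- .roi_frame(record$corners)
  px <- points$x + 0.5 - fr$origin[1]
  py <- points$y + 0.5 - fr$origin[2]
  lx <- px * fr$u[1] + py * fr$u[2] - 0.5
  ly <- px * fr$v[1] + py * fr$v[2] - 0.5
  outside <- which(lx < -0.5 | lx >= fr$w - 0.5 | ly < -0.5 | ly >= fr$h - 0.5)
  if (length(outside) > 0) {
    warning(sprintf("%d point(s) fall outside the ROI", length(outside)))
    if (drop_outside) {
      keep <- setdiff(seq_along(lx), outside)
      lx <- lx[keep]; ly <- ly[keep]
    }
  }
  out <- data.frame(roi_id = record$roi_id, x = lx, y = ly,
                    version = as.integer(version), annotator = annotator,
                    stringsAsFactors = FALSE)
  attr(out, "outside") <- outside
  class(out) <- c("PointAnnotation", class(out))
  out
}

#' Transform ROI-local points back into the WSI frame
#'
#' Inverse of [points_global_to_local()]; the round trip
#' global -> local -> global is accurate to within 1 px.
#'
#' @param points data.frame with columns `x`, `y` (ROI-local).
#' @param record an `ROIRecord`.
#' @return data.frame with WSI-frame `x`, `y`.
#' @export
points_local_to_global <- function(points, record) {
  fr <- .roi_frame(record$corners)
  gx <- fr$origin[1] + (points$x + 0.5) * fr$u[1] + (points$y + 0.5) * fr$v[1] - 0.5
  gy <- fr$origin[2] + (points$x + 0.5) * fr$u[2] + (points$y + 0.5) * fr$v[2] - 0.5
  data.frame(x = gx, y = gy)
}

#' Read or write point-annotation manifests
#'
#' CSV manifests carry columns roi_id, x, y, version, annotator.
#'
#' @param points a `PointAnnotation` data.frame.
#' @param path CSV path.
#' @return `write_annotations` returns the path invisibly;
#'   `read_annotations` returns the annotation data.frame.
#' @export
write_annotations <- function(points, path) {
  write.csv(as.data.frame(points)[, c("roi_id", "x", "y", "version", "annotator")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("PointAnnotation", class(out))
  out
}
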