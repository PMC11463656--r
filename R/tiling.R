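#' Build a tile grid over an ROI
#'
#' Lays a lattice of `tile` x `tile` windows at the given stride over
#' the ROI and labels each tile positive when at least one point
#' annotation falls inside its half-open extent
#' \[x, x+w) x \[y, y+h). The final row/column may be clipped to the
#' ROI border; clipped tiles are kept for inference coverage and
#' flagged so training-time sampling can exclude them.
#'
#' @param dims length-2 (H, W) of the ROI in px.
#' @param points data.frame with columns `x`, `y` (0-based), or NULL.
#' @param tile tile edge, px (default 1024).
#' @param stride lattice stride, px (default 1024, non-overlapping).
#' @param roi_id identifier recorded per row.
#' @return data.frame of class `TileIndex` with columns roi_id, x, y,
#'   w, h, clipped, has_nft; attributes `tile` and `stride`.
#' @export
build_tile_grid <- function(dims, points = NULL, tile = 1024, stride = 1024,
                            roi_id = "roi") {
  if (stride <= 0) stop("stride must be > 0")
  H <- dims[1]; W <- dims[2]
  xs <- seq(0, max(W - 1, 0), by = stride)
  ys <- seq(0, max(H - 1, 0), by = stride)
  grid <- expand.grid(x = xs, y = ys)
  grid$w <- pmin(tile, W - grid$x)
  grid$h <- pmin(tile, H - grid$y)
  grid$clipped <- grid$w < tile | grid$h < tile
  grid$has_nft <- FALSE
  if (!is.null(points) && nrow(points) > 0) {
    for (i in seq_len(nrow(grid))) {
      grid$has_nft[i] <- any(points$x >= grid$x[i] &
                             points$x < grid$x[i] + grid$w[i] &
                             points$y >= grid$y[i] &
                             points$y < grid$y[i] + grid$h[i])
    }
  }
  out <- data.frame(roi_id = roi_id, grid, stringsAsFactors = FALSE)
  attr(out, "tile") <- tile
  attr(out, "stride") <- stride
  class(out) <- c("TileIndex", class(out))
  out
}

#' Class-balanced tile sampling
#'
#' Draws tiles with replacement using inverse-class-frequency weights,
#' so each draw is positive (contains an NFT point) with probability
#' `positive_fraction` regardless of class imbalance — the sampling
#' contract used to counter the sparsity of NFT-bearing tiles during
#' training. Clipped border tiles are excluded from the sampling pool
#' by default (uniform tile shape for training).
#'
#' @param index a `TileIndex` from [build_tile_grid()].
#' @param n_draws number of tiles to draw.
#' @param positive_fraction target positive share per draw.
#' @param seed integer seed; draws are deterministic given it.
#' @param include_clipped admit clipped border tiles to the pool.
#' @return data.frame of sampled tile rows (with replacement).
#' @export
balanced_sample <- function(index, n_draws, positive_fraction = 0.5,
                            seed = NULL, include_clipped = FALSE) {
  pool <- if (include_clipped) index else index[!index$clipped, , drop = FALSE]
  npos <- sum(pool$has_nft); nneg <- sum(!pool$has_nft)
  if (npos == 0) stop("tile index has no positive tiles in the sampling pool")
  if (nneg == 0) stop("tile index has no negative tiles in the sampling pool")
  if (positive_fraction <= 0 || positive_fraction > 1)
    stop("positive_fraction must be in (0, 1]")
  w <- ifelse(pool$has_nft, positive_fraction / npos,
              (1 - positive_fraction) / nneg)
  if (!is.null(seed)) set.seed(seed)
  draws <- sample.int(nrow(pool), n_draws, replace = TRUE, prob = w)
  pool[draws, , drop = FALSE]
}

#' Write or read a tile index CSV
#' @param index a `TileIndex`.
#' @param path CSV path.
#' @return the path (write) or the index (read), invisibly/visibly.
#' @export
write_tile_index <- function(index, path) {
  write.csv(as.data.frame(index), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tile_index
#' @export
read_tile_index <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("TileIndex", class(out))
  out
}
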