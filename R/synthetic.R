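#' Specify a synthetic IHC object
#'
#' Describes one rendered object in a synthetic AT8-IHC scene: a
#' "flame-shaped" tangle (filled ellipse soma plus 0-2 tapered
#' protrusions along its orientation axis) or an off-criteria
#' distractor blob. Coordinates are 0-based (x = column, y = row).
#'
#' @param center length-2 numeric, object centre (x, y) in px.
#' @param soma_axes length-2 numeric, ellipse semi-axes (along, across
#'   orientation) in px; both must be >= 3.
#' @param orientation radians, direction of the long soma axis.
#' @param n_protrusions integer 0, 1 or 2.
#' @param protrusion_len protrusion length in px.
#' @param dab_od DAB optical density added inside the object (> 0).
#' @param nucleolus_offset length-2 numeric offset of the nucleolus
#'   from the soma centre, px.
#' @param is_nft logical; distractor objects carry no point annotation.
#' @return object of class `ObjectSpec`.
#' @export
object_spec <- function(center, soma_axes, orientation = 0,
                        n_protrusions = 1, protrusion_len = 60,
                        dab_od = 1.0, nucleolus_offset = c(0, 0),
                        is_nft = TRUE) {
  if (any(soma_axes <= 0)) stop("degenerate soma axes (<= 0)")
  if (any(soma_axes < 3)) stop("soma axes must be >= 3 px")
  if (!n_protrusions %in% 0:2) stop("n_protrusions must be 0, 1 or 2")
  if (dab_od <= 0) stop("dab_od must be > 0")
  structure(
    list(center = as.numeric(center), soma_axes = as.numeric(soma_axes),
         orientation = as.numeric(orientation),
         n_protrusions = as.integer(n_protrusions),
         protrusion_len = as.numeric(protrusion_len),
         dab_od = as.numeric(dab_od),
         nucleolus_offset = as.numeric(nucleolus_offset),
         is_nft = isTRUE(is_nft)),
    class = "ObjectSpec")
}

#' Rasterise a synthetic object mask
#'
#' Renders the flame shape of an [object_spec()] onto an `height` x
#' `width` canvas: a filled ellipse soma, plus tapered triangular
#' protrusions anchored just inside the soma tips so the result is a
#' single connected component containing the nucleolus point.
#'
#' @param spec an `ObjectSpec`.
#' @param height,width canvas dims in px.
#' @return logical height x width matrix.
#' @export
render_object_mask <- function(spec, height, width) {
  stopifnot(inherits(spec, "ObjectSpec"))
  cx <- spec$center[1]; cy <- spec$center[2]
  a <- spec$soma_axes[1]; b <- spec$soma_axes[2]
  th <- spec$orientation; L <- spec$protrusion_len
  ext <- ceiling(a + ifelse(spec$n_protrusions > 0, L, 0) + 2)
  # bounding subwindow (1-based row/col indices)
  r0 <- max(1L, floor(cy - ext) + 1L); r1 <- min(height, ceiling(cy + ext) + 1L)
  c0 <- max(1L, floor(cx - ext) + 1L); c1 <- min(width, ceiling(cx + ext) + 1L)
  mask <- matrix(FALSE, height, width)
  if (r0 > r1 || c0 > c1) return(mask)
  xs <- (c0:c1) - 1; ys <- (r0:r1) - 1     # 0-based pixel coords
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  sub <- (u / a)^2 + (v / b)^2 <= 1
  if (spec$n_protrusions > 0 && L > 0) {
    w0 <- 0.55 * b                          # base half-width of the taper
    dirs <- c(1, -1)[seq_len(spec$n_protrusions)]
    for (s in dirs) {
      uu <- s * u - (a - 2)                 # distance past the anchored base
      tri <- uu >= 0 & uu <= L & abs(v) <= w0 * (1 - uu / L)
      sub <- sub | tri
    }
  }
  mask[r0:r1, c0:c1] <- sub
  nuc <- round(spec$center + spec$nucleolus_offset)
  if (nuc[1] >= 0 && nuc[1] < width && nuc[2] >= 0 && nuc[2] < height &&
      !mask[nuc[2] + 1, nuc[1] + 1])
    stop("nucleolus point falls outside the rendered mask")
  mask
}

#' Render a synthetic AT8-IHC scene
#'
#' Composes objects in optical-density space (Beer-Lambert): every
#' pixel carries a background haematoxylin tissue tint, object pixels
#' add their DAB density, diffuse background tau is modelled as
#' salt-like DAB speckle (per-pixel Bernoulli at rate `noise`, low OD),
#' and optional Gaussian sensor noise is added in the 8-bit domain.
#' Scenes are bit-exact reproducible from (parameters, seed).
#'
#' @param objects list of [object_spec()] objects (may be empty).
#' @param dims length-2 integer (H, W).
#' @param noise fraction of pixels receiving diffuse DAB speckle,
#'   in \[0, 0.5).
#' @param seed integer RNG seed.
#' @param stains stain matrix shared with [rgb_to_hed()].
#' @param bg_h_od background haematoxylin optical density.
#' @param noise_od optical density of a speckle pixel.
#' @param gaussian_sd Gaussian sensor noise sd on the 8-bit scale
#'   (0 disables).
#' @param tissue optional logical H x W matrix marking the tissue
#'   region; pixels outside it render as clean white glass (no
#'   haematoxylin tint, no speckle). NULL = tissue everywhere.
#' @return object of class `SyntheticScene`: list with `rgb` (H x W x 3
#'   integer array, 0..255), `masks` (truth masks, is_nft objects),
#'   `distractor_masks`, `points` (data.frame x, y: one nucleolus per
#'   is_nft object), `objects`, `noise`, `seed`, `tissue`,
#'   `overlapping` flag.
#' @export
render_scene <- function(objects, dims, noise = 0, seed = 1,
                         stains = stain_matrix(), bg_h_od = 0.25,
                         noise_od = 0.35, gaussian_sd = 0, tissue = NULL) {
  if (noise < 0 || noise >= 0.5) stop("noise must be in [0, 0.5)")
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  od_dab <- matrix(0, H, W)
  cover <- matrix(0L, H, W)
  masks <- list(); dmasks <- list(); pts_x <- c(); pts_y <- c()
  for (sp in objects) {
    m <- render_object_mask(sp, H, W)
    od_dab <- od_dab + sp$dab_od * m
    cover <- cover + m
    if (sp$is_nft) {
      masks[[length(masks) + 1L]] <- m
      nuc <- round(sp$center + sp$nucleolus_offset)
      pts_x <- c(pts_x, nuc[1]); pts_y <- c(pts_y, nuc[2])
    } else dmasks[[length(dmasks) + 1L]] <- m
  }
  overlapping <- any(cover > 1L)
  if (is.null(tissue)) tissue <- matrix(TRUE, H, W)
  set.seed(seed)
  if (noise > 0)
    od_dab <- od_dab +
      noise_od * ((matrix(runif(H * W), H, W) < noise) & tissue)
  hed <- array(0, c(H, W, 3L))
  hed[, , 1] <- bg_h_od * tissue
  hed[, , 3] <- od_dab
  rgb <- hed_to_rgb(hed, stains, quantize = FALSE)
  if (gaussian_sd > 0)
    rgb <- rgb + array(rnorm(length(rgb), sd = gaussian_sd), dim(rgb))
  rgb <- round(pmin(pmax(rgb, 0), 255))
  storage.mode(rgb) <- "integer"
  structure(
    list(rgb = rgb, masks = masks, distractor_masks = dmasks,
         points = data.frame(x = as.numeric(pts_x), y = as.numeric(pts_y)),
         objects = objects, noise = noise, seed = as.integer(seed),
         tissue = tissue, overlapping = overlapping),
    class = "SyntheticScene")
}

#' @export
print.SyntheticScene <- function(x, ...) {
  cat(sprintf(
    "SyntheticScene %d x %d: %d NFT(s), %d distractor(s), noise %.3f, seed %d\n",
    nrow(x$rgb), ncol(x$rgb), length(x$masks), length(x$distractor_masks),
    x$noise, x$seed))
  invisible(x)
}

#' Generate a point-annotated synthetic ROI
#'
#' Places `n_nft` flame-shaped tangles (each carrying one nucleolus
#' point annotation) and `n_distractor` off-criteria blobs (smaller,
#' fainter, no protrusions, no point) at random positions with a
#' minimum centre separation, then renders the scene. Placement is by
#' rejection sampling; exceeding the retry budget raises a capacity
#' error.
#'
#' @param n_nft,n_distractor object counts.
#' @param dims length-2 (H, W) in px.
#' @param noise diffuse DAB speckle rate (see [render_scene()]).
#' @param seed integer seed controlling placement, shapes and noise.
#' @param min_sep minimum centre-to-centre separation, px.
#' @param margin minimum object-centre distance from the ROI border, px.
#' @param gaussian_sd 8-bit Gaussian sensor noise sd.
#' @param tissue_frac fraction of the canvas covered by tissue (a
#'   centred rectangle; the rest renders as white glass). Objects are
#'   placed inside the tissue region.
#' @param max_tries placement retry budget per scene.
#' @return a `SyntheticScene`.
#' @export
make_annotated_roi <- function(n_nft, n_distractor = 0, dims = c(1200, 1600),
                               noise = 0.01, seed = 1, min_sep = 300,
                               margin = 130, gaussian_sd = 2, tissue_frac = 1,
                               max_tries = 400 * (n_nft + n_distractor + 1)) {
  H <- dims[1]; W <- dims[2]
  if (tissue_frac <= 0 || tissue_frac > 1)
    stop("tissue_frac must be in (0, 1]")
  tissue <- NULL
  x_lo <- 0; x_hi <- W - 1; y_lo <- 0; y_hi <- H - 1
  if (tissue_frac < 1) {
    tw <- round(W * sqrt(tissue_frac)); th <- round(H * sqrt(tissue_frac))
    x_lo <- floor((W - tw) / 2); y_lo <- floor((H - th) / 2)
    x_hi <- x_lo + tw - 1; y_hi <- y_lo + th - 1
    tissue <- matrix(FALSE, H, W)
    tissue[(y_lo + 1):(y_hi + 1), (x_lo + 1):(x_hi + 1)] <- TRUE
  }
  if (x_hi - margin < x_lo + margin || y_hi - margin < y_lo + margin)
    stop("ROI too small for the placement margin")
  set.seed(seed)
  n_tot <- n_nft + n_distractor
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n_tot) {
    if (tries >= max_tries)
      stop(sprintf(
        "placement capacity exceeded: placed %d of %d objects after %d tries",
        nrow(centers), n_tot, tries))
    tries <- tries + 1L
    cand <- c(runif(1, x_lo + margin, x_hi - margin),
              runif(1, y_lo + margin, y_hi - margin))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2))) >= min_sep)
      centers <- rbind(centers, cand)
  }
  objects <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    if (i <= n_nft) {
      objects[[i]] <- object_spec(
        center = centers[i, ],
        soma_axes = c(runif(1, 45, 75), runif(1, 28, 45)),
        orientation = runif(1, 0, 2 * pi),
        n_protrusions = sample(1:2, 1),
        protrusion_len = runif(1, 40, 90),
        dab_od = runif(1, 0.85, 1.1),
        nucleolus_offset = runif(2, -8, 8),
        is_nft = TRUE)
    } else {
      objects[[i]] <- object_spec(
        center = centers[i, ],
        soma_axes = c(runif(1, 15, 30), runif(1, 12, 24)),
        orientation = runif(1, 0, 2 * pi),
        n_protrusions = 0,
        dab_od = runif(1, 0.5, 0.75),
        is_nft = FALSE)
    }
  }
  render_scene(objects, dims = c(H, W), noise = noise, seed = seed,
               gaussian_sd = gaussian_sd, tissue = tissue)
}

#' Write a synthetic scene to disk
#'
#' Saves the RGB image as PNG, each truth mask as a single-channel PNG,
#' and a JSON sidecar (points, object parameters, seed, noise).
#'
#' @param scene a `SyntheticScene`.
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @return invisibly, the sidecar path.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(aperm(array(scene$rgb / 255, dim(scene$rgb)), c(1, 2, 3)),
                file.path(dir, paste0(name, ".png")))
  for (i in seq_along(scene$masks))
    png::writePNG(scene$masks[[i]] * 1,
                  file.path(dir, sprintf("%s_mask_%03d.png", name, i)))
  side <- list(
    points = scene$points, noise = scene$noise, seed = scene$seed,
    overlapping = scene$overlapping,
    objects = lapply(scene$objects, function(o) o[setdiff(names(o), NULL)]))
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
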