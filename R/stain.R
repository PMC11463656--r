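#' Haematoxylin/eosin/DAB stain matrix
#'
#' Ruifrok-Johnston optical-density stain vectors for haematoxylin,
#' eosin and diaminobenzidine (DAB), row-normalised to unit Euclidean
#' length. Rows are stains, columns are RGB. The same matrix backs both
#' synthetic rendering and colour deconvolution so the unmixing round
#' trip is self-consistent.
#'
#' @return 3x3 numeric matrix with rownames `h`, `e`, `dab`.
#' @export
stain_matrix <- function() {
  m <- rbind(
    h   = c(0.65, 0.70, 0.29),
    e   = c(0.07, 0.99, 0.11),
    dab = c(0.27, 0.57, 0.78)
  )
  colnames(m) <- c("r", "g", "b")
  m / sqrt(rowSums(m^2))
}

.check_rgb <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3))
    stop("expected an H x W x 3 RGB array")
  invisible(dim(img))
}

#' Convert an 8-bit RGB tile to HED optical densities
#'
#' Computes per-pixel optical density OD = -log10(I / 255) (intensities
#' clamped to a floor of 1 before the log) and projects it onto the
#' inverse stain matrix, yielding haematoxylin, eosin and DAB density
#' channels. Pure white maps to OD ~ 0 in all channels.
#'
#' @param tile H x W x 3 array, values 0..255.
#' @param stains stain matrix as from [stain_matrix()].
#' @return H x W x 3 numeric array of stain optical densities
#'   (channels: h, e, dab).
#' @export
rgb_to_hed <- function(tile, stains = stain_matrix()) {
  d <- .check_rgb(tile)
  v <- pmax(as.numeric(tile), 1)
  od <- -log10(v / 255)
  dim(od) <- c(d[1] * d[2], 3L)
  hed <- od %*% solve(stains)
  dim(hed) <- d
  dimnames(hed) <- list(NULL, NULL, rownames(stains))
  hed
}

#' Render HED optical densities to 8-bit RGB (Beer-Lambert)
#'
#' Inverse of [rgb_to_hed()]: I = 255 * 10^(-OD %*% S), rounded and
#' clamped to 0..255. Used by the synthetic scene renderer.
#'
#' @param hed H x W x 3 array of stain optical densities.
#' @param stains stain matrix.
#' @param quantize round to 8-bit integers (default TRUE).
#' @return H x W x 3 RGB array.
#' @export
hed_to_rgb <- function(hed, stains = stain_matrix(), quantize = TRUE) {
  d <- .check_rgb(hed)
  v <- as.numeric(hed)
  dim(v) <- c(d[1] * d[2], 3L)
  rgb <- 255 * 10^(-(v %*% stains))
  rgb <- pmin(pmax(rgb, 0), 255)
  if (quantize) rgb <- round(rgb)
  dim(rgb) <- d
  rgb
}

#' Binarize the DAB channel of an IHC tile
#'
#' The DAB optical-density channel is min-max normalised to \[0, 1\],
#' Otsu-thresholded (256-bin histogram), binarized (>= threshold is
#' foreground) and cleaned by morphological opening then closing with a
#' disk structuring element. A constant DAB channel (e.g. an all-white
#' tile) degenerates Otsu; it yields an empty mask with a warning.
#'
#' @param tile H x W x 3 RGB array, values 0..255.
#' @param morph_radius disk structuring-element radius in px.
#' @param stains stain matrix.
#' @param min_range minimum DAB dynamic range (optical density) for a
#'   meaningful normalisation; below it the channel is effectively
#'   constant (min-max rescaling would only amplify 8-bit quantisation
#'   noise) and the tile degenerates to an empty mask.
#' @return object of class `DabMask`: list with `mask` (logical H x W),
#'   `dims`, `bounds` (min/max of the raw DAB channel) and `threshold`
#'   (Otsu cut on the normalised channel, NA when degenerate).
#' @export
dab_binary_mask <- function(tile, morph_radius = 3, stains = stain_matrix(),
                            min_range = 0.05) {
  d <- .check_rgb(tile)
  dab <- rgb_to_hed(tile, stains)[, , 3L]
  rng <- range(dab)
  if (diff(rng) < min_range) {
    warning("constant DAB channel: degenerate Otsu threshold, returning empty mask")
    return(structure(
      list(mask = matrix(FALSE, d[1], d[2]), dims = d[1:2],
           bounds = rng, threshold = NA_real_),
      class = "DabMask"))
  }
  norm <- (dab - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(norm, range = c(0, 1), levels = 256)
  bw <- (norm >= thr) * 1
  if (morph_radius > 0) {
    kern <- EBImage::makeBrush(2 * morph_radius + 1, shape = "disc")
    bw <- EBImage::closing(EBImage::opening(bw, kern), kern)
  }
  structure(
    list(mask = matrix(as.numeric(bw) > 0.5, d[1], d[2]), dims = d[1:2],
         bounds = rng, threshold = thr),
    class = "DabMask")
}

#' @export
print.DabMask <- function(x, ...) {
  cat(sprintf("DabMask %d x %d: %d foreground px, Otsu threshold %s\n",
              x$dims[1], x$dims[2], sum(x$mask),
              ifelse(is.na(x$threshold), "NA (degenerate)",
                     sprintf("%.4f", x$threshold))))
  invisible(x)
}

#' DAB burden proportion of an image
#'
#' Fraction of pixels called DAB-positive by [dab_binary_mask()]
#' (no centre-bias or blob-size filtering), normalised by the total
#' pixel count. Degenerate (constant-channel) inputs give 0.
#'
#' @inheritParams dab_binary_mask
#' @return scalar in \[0, 1\].
#' @export
dab_proportion <- function(tile, morph_radius = 3, stains = stain_matrix()) {
  dm <- withCallingHandlers(
    dab_binary_mask(tile, morph_radius = morph_radius, stains = stains),
    warning = function(w) {
      if (grepl("degenerate", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  sum(dm$mask) / length(dm$mask)
}
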