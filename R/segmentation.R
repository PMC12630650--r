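#' Construct an intensity raster
#'
#' A single-channel confocal intensity image with its pixel geometry. The
#' default pixel size corresponds to a 512 x 512 pixel field of view covering
#' 101.61 x 101.61 um^2.
#'
#' @param values Numeric or integer matrix of non-negative intensities,
#'   at least 16 x 16.
#' @param pixel_size Pixel edge length in um (> 0).
#' @param channel `"green"` or `"red"`.
#' @return A matrix of class `intensity_raster` with attributes `pixel_size`
#'   and `channel`.
#' @export
intensity_raster <- function(values, pixel_size = 101.61 / 512,
                             channel = c("green", "red")) {
  channel <- match.arg(channel)
  stopifnot(is.matrix(values))
  if (any(dim(values) < 16))
    stop("intensity_raster: dimensions must be at least 16 x 16")
  if (any(values < 0, na.rm = TRUE))
    stop("intensity_raster: intensities must be non-negative")
  if (!(pixel_size > 0)) stop("intensity_raster: pixel_size must be > 0")
  structure(values, pixel_size = pixel_size, channel = channel,
            class = c("intensity_raster", class(values)))
}

raster_values <- function(x) {
  v <- unclass(x)
  attr(v, "pixel_size") <- NULL
  attr(v, "channel") <- NULL
  v
}

#' Threshold an intensity raster into a foreground mask
#'
#' Intensity-based threshold segmentation: pixels strictly above the
#' threshold are foreground. The threshold is either computed automatically
#' by Otsu's method on a 256-bin histogram, or supplied as a fixed value
#' (the deterministic analogue of interactive thresholding). The threshold
#' actually used is recorded on the mask for reproducibility.
#'
#' @param raster An [intensity_raster()] or plain numeric matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value Threshold in intensity units; required for
#'   `method = "fixed"`.
#' @param provenance Label recorded on the mask, e.g. `"cell"` or `"lectin"`.
#' @return A logical matrix of class `mask` with attributes
#'   `threshold_used`, `method`, `provenance` and `pixel_size`.
#' @export
threshold_mask <- function(raster, method = c("otsu", "fixed"),
                           fixed_value = NULL, provenance = "cell") {
  method <- match.arg(method)
  v <- if (inherits(raster, "intensity_raster")) raster_values(raster)
       else raster
  stopifnot(is.matrix(v))
  px <- attr(raster, "pixel_size") %||% NA_real_
  if (method == "fixed") {
    if (is.null(fixed_value))
      stop("threshold_mask: method = 'fixed' requires fixed_value")
    th <- fixed_value
  } else {
    rng <- range(v)
    if (diff(rng) == 0)
      stop("threshold_mask: constant raster; Otsu threshold does not exist")
    u <- (v - rng[1]) / diff(rng)
    th <- rng[1] + EBImage::otsu(u, range = c(0, 1), levels = 256) * diff(rng)
  }
  m <- v > th
  structure(m, threshold_used = th, method = method, provenance = provenance,
            pixel_size = px, class = c("mask", class(m)))
}

new_mask <- function(m, provenance, threshold_used = NA_real_,
                     method = NA_character_, pixel_size = NA_real_) {
  stopifnot(is.matrix(m), is.logical(m))
  structure(m, threshold_used = threshold_used, method = method,
            provenance = provenance, pixel_size = pixel_size,
            class = c("mask", class(m)))
}

mask_values <- function(m) {
  v <- unclass(m)
  for (a in c("threshold_used", "method", "provenance", "pixel_size"))
    attr(v, a) <- NULL
  v
}

#' Dilate a mask by a 4-connected disc
#'
#' Morphological dilation with a diamond-shaped (4-connected disc)
#' structuring element of the given radius; radius 0 is the identity.
#'
#' @param mask A logical matrix (optionally of class `mask`).
#' @param radius_px Integer radius in pixels (>= 0).
#' @return Logical matrix of the same dimensions.
#' @export
dilate_mask <- function(mask, radius_px) {
  stopifnot(is.matrix(mask), radius_px >= 0)
  m <- mask_values(if (inherits(mask, "mask")) mask else
                     new_mask(mask, "cell"))
  if (radius_px == 0) return(m)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, "diamond")
  EBImage::dilate(m * 1, brush) > 0.5
}

#' Extracellular mask: complement of the (dilated) cell mask
#'
#' Removes microbial cells (and, through dilation, a safety margin around
#' them) from the image, leaving only extracellular biofilm areas.
#'
#' @param cell A `mask` with the segmented cell areas.
#' @param dilation_radius_px Dilation radius in pixels (default 1).
#' @return A `mask` with provenance `"extracellular"`.
#' @export
extracellular_mask <- function(cell, dilation_radius_px = 1) {
  stopifnot(inherits(cell, "mask"))
  out <- !dilate_mask(cell, dilation_radius_px)
  new_mask(out, provenance = "extracellular",
           pixel_size = attr(cell, "pixel_size"))
}

#' Partition a lectin mask into cell-associated and intercellular parts
#'
#' Lectin-stained pixels overlapping the cell mask dilated by
#' `dilation_radius_px` are cell-associated; the rest are intercellular.
#' The two parts are disjoint and their union is the input lectin mask
#' (partition identity), so areas are conserved exactly.
#'
#' @param lectin A `mask` of lectin-stained areas.
#' @param cell A congruent `mask` of cell areas.
#' @param dilation_radius_px Dilation radius in pixels (default 1).
#' @return A list with `mask` elements `cell_associated` and `intercellular`.
#' @export
partition_lectin <- function(lectin, cell, dilation_radius_px = 1) {
  stopifnot(inherits(lectin, "mask"), inherits(cell, "mask"),
            all(dim(lectin) == dim(cell)))
  dil <- dilate_mask(cell, dilation_radius_px)
  lv <- mask_values(lectin)
  px <- attr(lectin, "pixel_size")
  list(
    cell_associated = new_mask(lv & dil, "lectin_cell_associated",
                               pixel_size = px),
    intercellular = new_mask(lv & !dil, "lectin_intercellular",
                             pixel_size = px))
}

#' Area of a mask
#'
#' @param mask A `mask` (or logical matrix).
#' @param pixel_size Pixel edge length in um; defaults to the mask's own
#'   `pixel_size` attribute.
#' @return Area in um^2 (pixel count times pixel_size^2).
#' @export
mask_area_um2 <- function(mask, pixel_size = attr(mask, "pixel_size")) {
  if (is.null(pixel_size) || is.na(pixel_size))
    stop("mask_area_um2: pixel_size is unknown")
  sum(mask) * pixel_size^2
}
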