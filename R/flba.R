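#' Construct a two-channel confocal z-stack
#'
#' An ordered stack of two-channel optical slices spanning the height of a
#' biofilm, slice 1 adjacent to the substratum. The study layout acquires
#' 6 slices per stack (any n >= 2 is accepted); the lectin conjugate is
#' imaged in the green channel and the counterstained microbial cells in
#' the red channel.
#'
#' @param slices List of length >= 2; each element a list with congruent
#'   matrices `lectin` and `cells`.
#' @param interslice_um Distance between adjacent slices in um (> 0).
#' @param lectin_name Lectin identity, e.g. `"AAL"` (fucose-binding) or
#'   `"MNA-G"` (galactose-binding).
#' @param carrier_id,patient_id,treatment Metadata labels.
#' @param pixel_size Pixel edge length in um.
#' @return An object of class `zstack`.
#' @export
zstack <- function(slices, interslice_um = 2, lectin_name = "AAL",
                   carrier_id = "C1", patient_id = NA_character_,
                   treatment = NA_character_, pixel_size = 101.61 / 512) {
  stopifnot(is.list(slices), length(slices) >= 2, interslice_um > 0,
            pixel_size > 0)
  d0 <- dim(slices[[1]]$lectin)
  for (s in slices) {
    stopifnot(is.matrix(s$lectin), is.matrix(s$cells),
              all(dim(s$lectin) == d0), all(dim(s$cells) == d0))
  }
  structure(list(slices = slices, interslice_um = interslice_um,
                 lectin_name = lectin_name, carrier_id = carrier_id,
                 patient_id = patient_id, treatment = treatment,
                 pixel_size = pixel_size),
            class = "zstack")
}

# split slice indices into bottom / middle / top contiguous thirds;
# the 6-slice study layout gives {1-2}, {3-4}, {5-6}
slice_layers <- function(n) {
  cut(seq_len(n), 3, labels = c("bottom", "middle", "top"))
}

#' Biovolumes of microbial cells and lectin-stained matrix in a z-stack
#'
#' Per slice, both channels are segmented by intensity thresholding and the
#' lectin area is partitioned into cell-associated and intercellular parts
#' (lectin pixels within the dilated cell area vs. outside it). Pixel counts
#' are converted to areas through the pixel size and to volumes by
#' multiplying with the interslice distance; volumes are accumulated per
#' biofilm layer (bottom / middle / top thirds of the stack; slices 1-2,
#' 3-4, 5-6 for the 6-slice layout) and in total.
#'
#' @param stack A [zstack()].
#' @param method `"otsu"` or `"fixed"` (per channel via the fixed values).
#' @param fixed_lectin,fixed_cells Fixed thresholds in intensity units,
#'   required when `method = "fixed"`.
#' @param dilation_radius_px Radius defining "associated with microbial
#'   cells" (default 1 px).
#' @return An object of class `biovolume_report`: a list with named numeric
#'   vectors `microbial_um3`, `lectin_um3`, `cell_associated_um3`,
#'   `intercellular_um3` (components `bottom`, `middle`, `top`, `total`),
#'   a per-slice data frame `slices` (areas in um^2 and thresholds used),
#'   and the geometry (`interslice_um`, `pixel_size`, `dilation_radius_px`).
#'   Layer additivity (bottom + middle + top = total) and the partition
#'   identity (cell_associated + intercellular = lectin) hold exactly.
#' @export
stack_biovolumes <- function(stack, method = c("otsu", "fixed"),
                             fixed_lectin = NULL, fixed_cells = NULL,
                             dilation_radius_px = 1) {
  stopifnot(inherits(stack, "zstack"))
  method <- match.arg(method)
  n <- length(stack$slices)
  px2 <- stack$pixel_size^2
  dz <- stack$interslice_um
  layers <- slice_layers(n)

  per_slice <- lapply(seq_len(n), function(i) {
    sl <- stack$slices[[i]]
    cells <- tryCatch(
      threshold_mask(sl$cells, method = method, fixed_value = fixed_cells,
                     provenance = "cell"),
      error = function(e) stop("stack_biovolumes: slice ", i,
                               " cells channel: ", conditionMessage(e)))
    lectin <- tryCatch(
      threshold_mask(sl$lectin, method = method, fixed_value = fixed_lectin,
                     provenance = "lectin"),
      error = function(e) stop("stack_biovolumes: slice ", i,
                               " lectin channel: ", conditionMessage(e)))
    part <- partition_lectin(lectin, cells, dilation_radius_px)
    data.frame(
      slice = i, layer = as.character(layers[i]),
      microbial_um2 = sum(cells) * px2,
      lectin_um2 = sum(lectin) * px2,
      cell_associated_um2 = sum(part$cell_associated) * px2,
      intercellular_um2 = sum(part$intercellular) * px2,
      threshold_cells = attr(cells, "threshold_used"),
      threshold_lectin = attr(lectin, "threshold_used"),
      stringsAsFactors = FALSE)
  })
  slices <- do.call(rbind, per_slice)

  comp <- function(col) {
    v <- vapply(c("bottom", "middle", "top"), function(l)
      sum(slices[[col]][slices$layer == l]) * dz, numeric(1))
    c(v, total = sum(v))
  }
  report <- structure(list(
    microbial_um3 = comp("microbial_um2"),
    lectin_um3 = comp("lectin_um2"),
    cell_associated_um3 = comp("cell_associated_um2"),
    intercellular_um3 = comp("intercellular_um2"),
    slices = slices,
    interslice_um = dz, pixel_size = stack$pixel_size,
    dilation_radius_px = dilation_radius_px,
    lectin_name = stack$lectin_name, carrier_id = stack$carrier_id,
    patient_id = stack$patient_id, treatment = stack$treatment,
    normalized = NULL),
    class = "biovolume_report")
  check_biovolume_report(report)
  report
}

check_biovolume_report <- function(report, tol = 1e-9) {
  for (f in c("microbial_um3", "lectin_um3", "cell_associated_um3",
              "intercellular_um3")) {
    v <- report[[f]]
    stopifnot(abs(sum(v[c("bottom", "middle", "top")]) - v["total"]) <= tol)
  }
  stopifnot(all(abs(report$cell_associated_um3 + report$intercellular_um3 -
                    report$lectin_um3) <= tol))
  stopifnot(all(report$intercellular_um3 <= report$lectin_um3 + tol))
  invisible(TRUE)
}

#' Normalize lectin biovolumes by the microbial biovolume
#'
#' Expresses total and intercellular lectin-stained biovolumes as a
#' percentage of the microbial biovolume, overall and per layer. Per-layer
#' percentages use the layer-matched microbial biovolume as denominator by
#' default; percentages relative to the stack-total microbial biovolume are
#' emitted alongside (`*_totaldenom`). When a denominator is zero the
#' percentage is `NA` (undefined), never infinite.
#'
#' @param report A [stack_biovolumes()] report.
#' @param denominator `"layer"` (default) or `"total"`: which variant the
#'   `normalized_total_pct` / `normalized_intercellular_pct` fields carry.
#' @return The report with a `normalized` list: `normalized_total_pct` and
#'   `normalized_intercellular_pct` (components bottom/middle/top/total),
#'   plus the `*_totaldenom` variants.
#' @export
normalize_biovolumes <- function(report, denominator = c("layer", "total")) {
  stopifnot(inherits(report, "biovolume_report"))
  denominator <- match.arg(denominator)
  micro <- report$microbial_um3
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  layer_den <- micro
  total_den <- rep(micro["total"], 4)
  names(total_den) <- names(micro)
  den <- if (denominator == "layer") layer_den else total_den
  report$normalized <- list(
    normalized_total_pct = pct(report$lectin_um3, den),
    normalized_intercellular_pct = pct(report$intercellular_um3, den),
    normalized_total_pct_totaldenom = pct(report$lectin_um3, total_den),
    normalized_intercellular_pct_totaldenom =
      pct(report$intercellular_um3, total_den),
    denominator = denominator)
  report
}

#' Biofilm thickness from slice occupancy
#'
#' The number of slices whose microbial area fraction reaches the occupancy
#' threshold, times the interslice distance. A pragmatic operational
#' definition of the height spanned by the biofilm within the stack.
#'
#' @param stack A [zstack()].
#' @param occupancy_threshold Minimum microbial area fraction for a slice to
#'   count as occupied (default 0.005, i.e. 0.5 percent).
#' @param method,fixed_cells Passed to [threshold_mask()] for the cells
#'   channel.
#' @return Thickness in um.
#' @export
thickness <- function(stack, occupancy_threshold = 0.005,
                      method = c("otsu", "fixed"), fixed_cells = NULL) {
  stopifnot(inherits(stack, "zstack"))
  method <- match.arg(method)
  occ <- vapply(stack$slices, function(sl) {
    m <- threshold_mask(sl$cells, method = method, fixed_value = fixed_cells,
                        provenance = "cell")
    mean(m)
  }, numeric(1))
  sum(occ >= occupancy_threshold) * stack$interslice_um
}

#' Coefficient of variation across fields of view
#'
#' Sample SD divided by the mean; used to quantify the variability of pH or
#' normalized biovolume between fields of view of the same biofilm. Scale
#' invariant: cv(k x) = cv(x) for k > 0.
#'
#' @param values Numeric vector, length >= 2.
#' @return The coefficient of variation, or `NA` (with a warning) when the
#'   mean is zero.
#' @export
fov_variability <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  m <- mean(values)
  if (m == 0) {
    warning("fov_variability: mean is zero; CV undefined")
    return(NA_real_)
  }
  stats::sd(values) / m
}

#' @export
print.biovolume_report <- function(x, ...) {
  cat(sprintf("biovolume_report [%s, carrier %s]: %d slices, dz = %g um\n",
              x$lectin_name, x$carrier_id, nrow(x$slices), x$interslice_um))
  m <- rbind(microbial = x$microbial_um3, lectin = x$lectin_um3,
             intercellular = x$intercellular_um3)
  print(round(m, 2))
  if (!is.null(x$normalized)) {
    cat(sprintf("normalized (%s denominator): total %.1f%%, intercellular %.1f%%\n",
                x$normalized$denominator,
                x$normalized$normalized_total_pct["total"],
                x$normalized$normalized_intercellular_pct["total"]))
  }
  invisible(x)
}
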