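#' Construct a two-channel ratiometric field of view
#'
#' Paired green and red intensity rasters for one laser-marked field of view
#' of a dye-stained biofilm, imaged at a fixed time after the start of a
#' sucrose challenge.
#'
#' @param green,red Congruent [intensity_raster()] objects (plain matrices
#'   are wrapped with the default pixel size).
#' @param fov_id,carrier_id Labels identifying the field of view and the
#'   biofilm carrier it sits on.
#' @param timepoint_min Minutes of sucrose exposure at acquisition; the
#'   study design uses 10 and 35. `NA` is allowed for calibration buffers.
#' @return An object of class `ratio_fov`.
#' @export
ratio_fov <- function(green, red, fov_id = "FOV1", carrier_id = "C1",
                      timepoint_min = NA_real_) {
  if (!inherits(green, "intensity_raster"))
    green <- intensity_raster(green, channel = "green")
  if (!inherits(red, "intensity_raster"))
    red <- intensity_raster(red, channel = "red")
  stopifnot(all(dim(green) == dim(red)))
  if (!is.na(timepoint_min) && !timepoint_min %in% c(10, 35))
    stop("ratio_fov: timepoint_min must be 10, 35 or NA")
  structure(list(green = green, red = red, fov_id = fov_id,
                 carrier_id = carrier_id, timepoint_min = timepoint_min),
            class = "ratio_fov")
}

#' Per-pixel green/red ratio over the extracellular area
#'
#' Computes the green/red intensity ratio at every extracellular pixel.
#' Pixels outside the extracellular mask, and pixels whose red intensity is
#' zero (undefined ratio), are `NA`. A field of view whose extracellular
#' mask is empty is marked unreportable rather than raising an error, so
#' cohort processing never aborts on a single dense image.
#'
#' @param fov A [ratio_fov()].
#' @param extracellular A congruent `mask` (from [extracellular_mask()]).
#' @return A numeric matrix of class `ratio_map` with attributes `n_valid`,
#'   `reportable`, `fov_id`, `carrier_id`, `timepoint_min`, `pixel_size`.
#' @export
ratio_map <- function(fov, extracellular) {
  stopifnot(inherits(fov, "ratio_fov"), inherits(extracellular, "mask"),
            all(dim(fov$green) == dim(extracellular)))
  g <- raster_values(fov$green)
  r <- raster_values(fov$red)
  m <- mask_values(extracellular)
  ratio <- matrix(NA_real_, nrow(g), ncol(g))
  use <- m & r > 0
  ratio[use] <- g[use] / r[use]
  structure(ratio, n_valid = sum(use), reportable = sum(use) > 0,
            fov_id = fov$fov_id, carrier_id = fov$carrier_id,
            timepoint_min = fov$timepoint_min,
            pixel_size = attr(fov$green, "pixel_size"),
            class = c("ratio_map", "matrix", "array"))
}

#' Summarize one field of view: mean and SD of extracellular pH
#'
#' Converts every valid ratio pixel to pH through the calibration curve,
#' then averages in pH units (conversion first, averaging second — the two
#' orders are not equivalent under the nonlinear curve). Pixels converting
#' to a pH outside the calibrated domain are excluded from the mean and SD;
#' their fraction is reported instead of being silently clamped.
#'
#' @param ratios A `ratio_map` (or plain matrix of ratios with `NA` for
#'   invalid pixels).
#' @param curve A [calibration_curve()].
#' @param fov_id,carrier_id,timepoint_min Metadata; default to the
#'   attributes carried by the `ratio_map`.
#' @return A one-row data frame: `fov_id`, `carrier_id`, `timepoint_min`,
#'   `mean_ph`, `sd_ph`, `n_pixels` (pixels entering the mean),
#'   `valid_fraction` (valid ratio pixels / all pixels),
#'   `out_of_domain_fraction` (among converted pixels), `reportable`.
#' @export
fov_summary <- function(ratios, curve,
                        fov_id = attr(ratios, "fov_id") %||% NA_character_,
                        carrier_id = attr(ratios, "carrier_id") %||% NA_character_,
                        timepoint_min = attr(ratios, "timepoint_min") %||% NA_real_) {
  stopifnot(inherits(curve, "calibration_curve"))
  ph <- ph_from_ratio(as.numeric(ratios), curve)
  converted <- ph[!is.na(ph)]
  in_dom <- converted[converted >= curve$domain[1] &
                      converted <= curve$domain[2]]
  n <- length(in_dom)
  data.frame(
    fov_id = fov_id, carrier_id = carrier_id, timepoint_min = timepoint_min,
    mean_ph = if (n > 0) mean(in_dom) else NA_real_,
    sd_ph = if (n > 1) stats::sd(in_dom) else if (n == 1) 0 else NA_real_,
    n_pixels = n,
    valid_fraction = length(converted) / length(ratios),
    out_of_domain_fraction =
      if (length(converted) > 0) 1 - n / length(converted) else NA_real_,
    reportable = n > 0,
    stringsAsFactors = FALSE)
}

#' Process one field of view end to end
#'
#' Convenience chain for a single ratiometric field of view: segment
#' microbial cells by intensity thresholding on one channel, remove them
#' (with a dilation margin) to obtain the extracellular mask, compute the
#' green/red ratio map, and summarize extracellular pH.
#'
#' @param fov A [ratio_fov()].
#' @param curve A [calibration_curve()].
#' @param cell_channel Channel used to segment cells (`"red"` default: the
#'   counterstained cells are bright in both channels).
#' @param method,fixed_value Passed to [threshold_mask()].
#' @param dilation_radius_px Margin around cells (default 1 px).
#' @return A list: `summary` (one-row data frame from [fov_summary()]),
#'   `ratios` (the `ratio_map`), `cell_mask`, `extracellular`.
#' @export
process_fov <- function(fov, curve, cell_channel = c("red", "green"),
                        method = c("otsu", "fixed"), fixed_value = NULL,
                        dilation_radius_px = 1) {
  cell_channel <- match.arg(cell_channel)
  method <- match.arg(method)
  cells <- threshold_mask(fov[[cell_channel]], method = method,
                          fixed_value = fixed_value, provenance = "cell")
  extra <- extracellular_mask(cells, dilation_radius_px)
  ratios <- ratio_map(fov, extra)
  list(summary = fov_summary(ratios, curve), ratios = ratios,
       cell_mask = cells, extracellular = extra)
}

#' Mean pH of one biofilm over its fields of view
#'
#' Unweighted mean of the per-FOV mean pH values (the study images 9
#' laser-marked FOVs per biofilm); unreportable FOVs are dropped.
#'
#' @param fovs Data frame of [fov_summary()] rows for one biofilm.
#' @return A one-row data frame: `mean_ph`, `n_fov`.
#' @export
biofilm_ph <- function(fovs) {
  stopifnot(is.data.frame(fovs), "mean_ph" %in% names(fovs))
  ok <- if ("reportable" %in% names(fovs)) fovs$reportable &
          !is.na(fovs$mean_ph) else !is.na(fovs$mean_ph)
  if (!any(ok)) stop("biofilm_ph: no reportable FOV")
  data.frame(mean_ph = mean(fovs$mean_ph[ok]), n_fov = sum(ok))
}

#' Aggregate FOV summaries to biofilm means across a cohort
#'
#' @param fovs Data frame of [fov_summary()] rows augmented with
#'   `patient_id` and `treatment` columns (one `carrier_id` = one biofilm).
#' @return Data frame with one row per biofilm x timepoint:
#'   `patient_id`, `treatment`, `carrier_id`, `timepoint_min`, `mean_ph`,
#'   `n_fov`.
#' @export
cohort_biofilm_ph <- function(fovs) {
  stopifnot(all(c("patient_id", "treatment", "carrier_id", "timepoint_min",
                  "mean_ph") %in% names(fovs)))
  ok <- if ("reportable" %in% names(fovs)) fovs$reportable else
          !is.na(fovs$mean_ph)
  fovs <- fovs[ok & !is.na(fovs$mean_ph), , drop = FALSE]
  key <- interaction(fovs$patient_id, fovs$treatment, fovs$carrier_id,
                     fovs$timepoint_min, drop = TRUE)
  out <- do.call(rbind, lapply(split(fovs, key), function(d)
    data.frame(patient_id = d$patient_id[1], treatment = d$treatment[1],
               carrier_id = d$carrier_id[1],
               timepoint_min = d$timepoint_min[1],
               mean_ph = mean(d$mean_ph), n_fov = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Paired per-patient pH differences (treatment minus placebo)
#'
#' For each patient and timepoint, averages the biofilm mean pH over the
#' duplicate biofilms of each treatment side and forms the within-patient
#' difference ARG - NoARG. Patients missing one side at a timepoint are
#' excluded with a message.
#'
#' @param biofilms Data frame as returned by [cohort_biofilm_ph()] (columns
#'   `patient_id`, `treatment` in `{"ARG", "NoARG"}`, `timepoint_min`,
#'   `mean_ph`).
#' @return Data frame with one row per patient x timepoint: `patient_id`,
#'   `timepoint_min`, `ph_arg`, `ph_noarg`, `delta_ph` (= ph_arg - ph_noarg).
#' @export
paired_delta_ph <- function(biofilms) {
  stopifnot(all(c("patient_id", "treatment", "timepoint_min", "mean_ph")
                %in% names(biofilms)))
  stopifnot(all(biofilms$treatment %in% c("ARG", "NoARG")))
  key <- interaction(biofilms$patient_id, biofilms$timepoint_min, drop = TRUE)
  rows <- lapply(split(biofilms, key), function(d) {
    arg <- d$mean_ph[d$treatment == "ARG"]
    noarg <- d$mean_ph[d$treatment == "NoARG"]
    if (length(arg) == 0 || length(noarg) == 0) {
      message("paired_delta_ph: patient ", d$patient_id[1], " timepoint ",
              d$timepoint_min[1], " lacks one treatment side; excluded")
      return(NULL)
    }
    data.frame(patient_id = d$patient_id[1],
               timepoint_min = d$timepoint_min[1],
               ph_arg = mean(arg), ph_noarg = mean(noarg),
               delta_ph = mean(arg) - mean(noarg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("paired_delta_ph: no complete patient pairs")
  rownames(out) <- NULL
  out[order(out$patient_id, out$timepoint_min), , drop = FALSE]
}
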