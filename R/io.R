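#' Read a two-channel field of view from a TIFF file
#'
#' Reads a two-page TIFF (page 1 = green, page 2 = red by default) into a
#' [ratio_fov()]. Intensities are kept as integers at the stored bit depth
#' until ratio computation.
#'
#' @param path TIFF file path.
#' @param pixel_size Pixel edge length in um.
#' @param channels Named integer vector mapping `green` and `red` to page
#'   numbers.
#' @param fov_id,carrier_id,timepoint_min Metadata attached to the FOV.
#' @return A [ratio_fov()].
#' @export
read_fov_tiff <- function(path, pixel_size = 101.61 / 512,
                          channels = c(green = 1L, red = 2L),
                          fov_id = basename(path), carrier_id = NA_character_,
                          timepoint_min = NA_real_) {
  pages <- read_tiff_pages(path)
  if (length(pages) < max(channels))
    stop("read_fov_tiff: ", path, " has ", length(pages),
         " page(s); need at least ", max(channels))
  ratio_fov(intensity_raster(pages[[channels[["green"]]]], pixel_size,
                             "green"),
            intensity_raster(pages[[channels[["red"]]]], pixel_size, "red"),
            fov_id = fov_id, carrier_id = carrier_id,
            timepoint_min = timepoint_min)
}

#' Read a two-channel z-stack from a multi-page TIFF
#'
#' Pages are interpreted as slice-interleaved channel pairs
#' (lectin_1, cells_1, lectin_2, cells_2, ...), slice 1 adjacent to the
#' substratum.
#'
#' @param path TIFF file path (2 x n_slices pages).
#' @param n_slices Number of slices expected (default 6).
#' @param interslice_um Interslice distance in um.
#' @param pixel_size Pixel edge length in um.
#' @param lectin_name,carrier_id,patient_id,treatment Metadata.
#' @return A [zstack()].
#' @export
read_zstack_tiff <- function(path, n_slices = 6, interslice_um = 2,
                             pixel_size = 101.61 / 512, lectin_name = "AAL",
                             carrier_id = NA_character_,
                             patient_id = NA_character_,
                             treatment = NA_character_) {
  pages <- read_tiff_pages(path)
  if (length(pages) != 2 * n_slices)
    stop("read_zstack_tiff: ", path, " has ", length(pages),
         " page(s); expected ", 2 * n_slices)
  slices <- lapply(seq_len(n_slices), function(i)
    list(lectin = pages[[2 * i - 1]], cells = pages[[2 * i]]))
  zstack(slices, interslice_um = interslice_um, lectin_name = lectin_name,
         carrier_id = carrier_id, patient_id = patient_id,
         treatment = treatment, pixel_size = pixel_size)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path, " does not exist")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("cannot read TIFF ", path, ": ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' Write a field of view / z-stack as 8-bit TIFF
#'
#' Intensities are clipped to [0, 255] and stored at 8 bits per sample.
#'
#' @param fov A [ratio_fov()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fov_tiff <- function(fov, path) {
  stopifnot(inherits(fov, "ratio_fov"))
  g <- clip8(raster_values(fov$green))
  r <- clip8(raster_values(fov$red))
  tiff::writeTIFF(list(g / 255, r / 255), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_fov_tiff
#' @param stack A [zstack()].
#' @export
write_zstack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  pages <- unlist(lapply(stack$slices, function(s)
    list(clip8(s$lectin) / 255, clip8(s$cells) / 255)), recursive = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' @param path Manifest CSV path.
#' @param base_dir Directory image paths are relative to (defaults to the
#'   manifest's directory).
#' @param required Required column names.
#' @return The manifest data frame with an absolute `path` column.
#' @export
read_manifest <- function(path, base_dir = dirname(path),
                          required = c("patient_id", "treatment",
                                       "carrier_id", "fov_id", "path")) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0)
    stop("read_manifest: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(m$treatment %in% c("ARG", "NoARG")))
    stop("read_manifest: treatment must be 'ARG' or 'NoARG'")
  key_cols <- intersect(c("carrier_id", "fov_id", "timepoint_min"), names(m))
  key <- do.call(paste, m[key_cols])
  if (anyDuplicated(key))
    stop("read_manifest: duplicated (carrier, fov, timepoint) rows")
  m$path <- file.path(base_dir, m$path)
  absent <- !file.exists(m$path)
  if (any(absent))
    stop("read_manifest: missing image file(s): ",
         paste(utils::head(m$path[absent], 3), collapse = ", "))
  m
}

round_num <- function(d, digits = 6) {
  for (j in seq_along(d)) if (is.numeric(d[[j]])) d[[j]] <- round(d[[j]], digits)
  d
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Orchestrates every stage on a directory laid out as written by
#' [gen_cohort()]: per-FOV ratiometric pH (segmentation, ratio map,
#' calibration conversion), biofilm and paired per-patient pH aggregation,
#' z-stack biovolume quantification with normalization, and the ASV
#' statistics (paired differential abundance and PCA). All results are
#' written as tidy CSV files with numeric columns at fixed precision, so a
#' rerun on the same inputs is byte-identical.
#'
#' @param cohort_dir Directory containing `manifest_ph.csv`,
#'   `manifest_flba.csv`, `asv_counts.csv`, `asv_meta.csv` and `curve.json`
#'   (any arm may be absent; present arms are run).
#' @param out_dir Output directory (created if needed).
#' @param curve Optional [calibration_curve()]; defaults to
#'   `curve.json` in `cohort_dir`.
#' @param pixel_size Pixel edge length in um for image reading.
#' @param dilation_radius_px Cell-margin radius for both arms.
#' @param min_mean_abundance_pct Abundance filter for differential
#'   abundance.
#' @return Invisibly, a list of the result data frames (`fov_ph`,
#'   `biofilm_ph`, `delta_ph`, `flba`, `diff_abundance`, `pca_scores`),
#'   each of which is also written to `out_dir`.
#' @export
run_pipeline <- function(cohort_dir, out_dir,
                         curve = NULL, pixel_size = 101.61 / 512,
                         dilation_radius_px = 1,
                         min_mean_abundance_pct = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  if (is.null(curve)) {
    cj <- file.path(cohort_dir, "curve.json")
    if (!file.exists(cj))
      stop("run_pipeline: no curve supplied and no curve.json in ",
           cohort_dir)
    curve <- read_curve_json(cj)
  }

  mf_ph <- file.path(cohort_dir, "manifest_ph.csv")
  if (file.exists(mf_ph)) {
    man <- read_manifest(mf_ph, base_dir = cohort_dir,
                         required = c("patient_id", "treatment", "carrier_id",
                                      "fov_id", "timepoint_min", "path"))
    fov_rows <- lapply(seq_len(nrow(man)), function(i) {
      fov <- read_fov_tiff(man$path[i], pixel_size = pixel_size,
                           fov_id = man$fov_id[i],
                           carrier_id = man$carrier_id[i],
                           timepoint_min = man$timepoint_min[i])
      s <- process_fov(fov, curve,
                       dilation_radius_px = dilation_radius_px)$summary
      cbind(man[i, c("patient_id", "treatment")], s)
    })
    fov_ph <- do.call(rbind, fov_rows)
    rownames(fov_ph) <- NULL
    results$fov_ph <- fov_ph
    results$biofilm_ph <- cohort_biofilm_ph(fov_ph)
    results$delta_ph <- paired_delta_ph(results$biofilm_ph)
    utils::write.csv(round_num(fov_ph),
                     file.path(out_dir, "fov_ph.csv"), row.names = FALSE)
    utils::write.csv(round_num(results$biofilm_ph),
                     file.path(out_dir, "biofilm_ph.csv"), row.names = FALSE)
    utils::write.csv(round_num(results$delta_ph),
                     file.path(out_dir, "delta_ph.csv"), row.names = FALSE)
  }

  mf_fl <- file.path(cohort_dir, "manifest_flba.csv")
  if (file.exists(mf_fl)) {
    man <- read_manifest(mf_fl, base_dir = cohort_dir,
                         required = c("patient_id", "treatment", "lectin",
                                      "carrier_id", "fov_id",
                                      "interslice_um", "path"))
    rows <- lapply(seq_len(nrow(man)), function(i) {
      stk <- read_zstack_tiff(man$path[i],
                              interslice_um = man$interslice_um[i],
                              pixel_size = pixel_size,
                              lectin_name = man$lectin[i],
                              carrier_id = man$carrier_id[i],
                              patient_id = man$patient_id[i],
                              treatment = man$treatment[i])
      rep <- normalize_biovolumes(
        stack_biovolumes(stk, dilation_radius_px = dilation_radius_px))
      comps <- c("bottom", "middle", "top", "total")
      data.frame(
        patient_id = man$patient_id[i], treatment = man$treatment[i],
        lectin = man$lectin[i], carrier_id = man$carrier_id[i],
        fov_id = man$fov_id[i], layer = rep(comps, times = 4),
        measure = rep(c("microbial_um3", "lectin_um3", "intercellular_um3",
                        "normalized_intercellular_pct"), each = 4),
        value = c(rep$microbial_um3[comps], rep$lectin_um3[comps],
                  rep$intercellular_um3[comps],
                  rep$normalized$normalized_intercellular_pct[comps]),
        stringsAsFactors = FALSE)
    })
    results$flba <- do.call(rbind, rows)
    rownames(results$flba) <- NULL
    utils::write.csv(round_num(results$flba),
                     file.path(out_dir, "flba_biovolumes.csv"),
                     row.names = FALSE)
  }

  cf <- file.path(cohort_dir, "asv_counts.csv")
  mf <- file.path(cohort_dir, "asv_meta.csv")
  if (file.exists(cf) && file.exists(mf)) {
    counts <- utils::read.csv(cf, check.names = FALSE)
    rn <- counts$sample_id
    counts <- as.matrix(counts[setdiff(names(counts), "sample_id")])
    rownames(counts) <- rn
    meta <- utils::read.csv(mf, stringsAsFactors = FALSE)
    meta <- meta[match(rn, meta$sample_id), ]
    tab <- asv_table(counts, meta$patient_id, meta$treatment)
    da <- paired_differential_abundance(
      tab, min_mean_abundance_pct = min_mean_abundance_pct)
    results$diff_abundance <- da
    utils::write.csv(round_num(as.data.frame(da)),
                     file.path(out_dir, "diff_abundance.csv"),
                     row.names = FALSE)
    pc <- pca_clr(tab)
    scores <- data.frame(sample_id = rownames(pc$scores),
                         patient_id = tab$meta$patient_id,
                         treatment = tab$meta$treatment,
                         pc$scores[, seq_len(min(5, ncol(pc$scores)))])
    results$pca_scores <- scores
    utils::write.csv(round_num(scores),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  }

  invisible(results)
}
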