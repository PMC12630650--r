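#' Deterministic substream seed
#'
#' Derives a child seed from a top-level seed and a string tag, so that
#' every generated unit (patient, carrier, FOV) draws from its own named
#' substream and partial regeneration is stable.
#'
#' @param seed Integer top-level seed.
#' @param ... Components of the tag (coerced to character, joined by "/").
#' @return An integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer((seed %% 2147483647 + h) %% 2147483647)
}

clip8 <- function(x) pmin(pmax(round(x), 0), 255)

apply_noise <- function(mean_img, poisson, read_noise_sd, quantize) {
  x <- mean_img
  if (poisson) x[] <- stats::rpois(length(x), pmax(as.numeric(x), 0))
  if (read_noise_sd > 0) x <- x + stats::rnorm(length(x), 0, read_noise_sd)
  if (quantize) x[] <- clip8(x)
  x
}

#' Generate a calibration buffer image set with ground truth
#'
#' Emulates the dye calibration series: buffers titrated from pH 4.0 to 8.0
#' in 0.2-unit steps, each imaged in several fields of view. Each FOV is a
#' cell-free image pair with a constant red raster and a green raster equal
#' to (true ratio + Gaussian noise) times the red intensity, so that the
#' per-pixel green/red ratio is the forward calibration relation plus noise.
#'
#' @param curve A [calibration_curve()]; defaults to the published
#'   C-SNARF-4 constants.
#' @param noise_sd SD of the Gaussian noise added to the per-pixel ratio
#'   (>= 0; 0 gives noiseless images).
#' @param n_fov FOVs per buffer (default 3).
#' @param ph Buffer pH levels (default 4.0 to 8.0 by 0.2; 21 levels).
#' @param dim Image dimensions (default 512 x 512).
#' @param red_intensity Constant red raster value.
#' @param seed Integer seed (substreamed per level and FOV).
#' @return A list: `images` (named list per pH level of [ratio_fov()]
#'   lists, suitable for [calibration_from_images()]) and `truth`
#'   (data frame `ph`, `true_ratio`).
#' @export
gen_calibration_set <- function(curve = csnarf4_curve(), noise_sd = 0.01,
                                n_fov = 3, ph = seq(4, 8, by = 0.2),
                                dim = c(512, 512), red_intensity = 90,
                                seed = 1) {
  stopifnot(noise_sd >= 0, n_fov >= 1)
  true_ratio <- ratio_from_ph(ph, curve)
  images <- lapply(seq_along(ph), function(i) {
    lapply(seq_len(n_fov), function(f) {
      withr::with_seed(substream_seed(seed, "cal", ph[i], f), {
        ratio <- true_ratio[i] +
          if (noise_sd > 0) stats::rnorm(prod(dim), 0, noise_sd) else 0
        red <- matrix(red_intensity, dim[1], dim[2])
        green <- matrix(ratio * red_intensity, dim[1], dim[2])
        ratio_fov(intensity_raster(green, channel = "green"),
                  intensity_raster(red, channel = "red"),
                  fov_id = sprintf("cal_%0.1f_%d", ph[i], f),
                  carrier_id = "calibration")
      })
    })
  })
  names(images) <- as.character(ph)
  list(images = images,
       truth = data.frame(ph = ph, true_ratio = true_ratio))
}

draw_ellipses <- function(dim, target_fraction, axis_range = c(2, 6)) {
  mask <- matrix(FALSE, dim[1], dim[2])
  if (target_fraction <= 0) return(mask)
  npx <- prod(dim)
  target_px <- target_fraction * npx
  covered <- 0
  max_tries <- ceiling(10 * target_px / (pi * mean(axis_range)^2) + 20)
  for (k in seq_len(max_tries)) {
    if (covered >= target_px) break
    cx <- stats::runif(1, 1, dim[1])
    cy <- stats::runif(1, 1, dim[2])
    a1 <- stats::runif(1, axis_range[1], axis_range[2])
    a2 <- stats::runif(1, axis_range[1], axis_range[2])
    th <- stats::runif(1, 0, pi)
    r <- max(a1, a2)
    ix <- max(1, floor(cx - r)):min(dim[1], ceiling(cx + r))
    iy <- max(1, floor(cy - r)):min(dim[2], ceiling(cy + r))
    dx <- outer(ix - cx, rep(1, length(iy)))
    dy <- outer(rep(1, length(ix)), iy - cy)
    u <- (dx * cos(th) + dy * sin(th)) / a1
    v <- (-dx * sin(th) + dy * cos(th)) / a2
    block <- mask[ix, iy] | (u^2 + v^2 <= 1)
    covered <- covered + sum(block) - sum(mask[ix, iy])
    mask[ix, iy] <- block
  }
  mask
}

# 4-connected cross mean with replicated edges: a one-pixel smoothing rim
# whose support matches the diamond structuring element used for dilation,
# so a one-pixel cell margin always covers the rim
cross_mean <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  p <- x[c(1, seq_len(n1), n1), c(1, seq_len(n2), n2)]
  i <- seq_len(n1); j <- seq_len(n2)
  (p[i + 1, j + 1] + p[i, j + 1] + p[i + 2, j + 1] +
     p[i + 1, j] + p[i + 1, j + 2]) / 5
}

# smooth Gaussian-like random field: coarse white noise bilinearly
# interpolated to full resolution (correlation length ~ step pixels)
smooth_field <- function(dim, step = 8) {
  interp <- function(n, nc) {
    pos <- (seq_len(n) - 1) / step
    i0 <- pmin(floor(pos) + 1, nc - 1)
    w <- pos - (i0 - 1)
    a <- matrix(0, n, nc)
    a[cbind(seq_len(n), i0)] <- 1 - w
    a[cbind(seq_len(n), i0 + 1)] <- w
    a
  }
  n1c <- ceiling((dim[1] - 1) / step) + 2
  n2c <- ceiling((dim[2] - 1) / step) + 2
  z <- matrix(stats::rnorm(n1c * n2c), n1c, n2c)
  interp(dim[1], n1c) %*% z %*% t(interp(dim[2], n2c))
}

#' Generate a ratiometric dye field of view with known pH field
#'
#' Builds a ground-truth pH field (constant, two-region, or smooth
#' horizontal gradient), encodes it in the extracellular green/red ratio
#' through the forward calibration relation, overlays microbial cell
#' objects (random ellipses, bright in both channels with a one-pixel
#' smoothed edge so that intensity thresholding removes them), and applies
#' Poisson shot noise plus Gaussian read noise. With all noise disabled the
#' image encodes the field exactly (no quantization), enabling pixel-exact
#' recovery checks.
#'
#' @param ph_field `"constant"`, `"two_region"`, `"gradient"`, or a numeric
#'   matrix of pH values (must lie within the curve domain).
#' @param mean_ph Field value for `"constant"`.
#' @param ph_levels Length-2 values for `"two_region"` (left/right halves)
#'   or the range for `"gradient"`.
#' @param cell_density Target cell area fraction in [0, 1); 1 or more is an
#'   error (no extracellular pixels would remain).
#' @param curve A [calibration_curve()].
#' @param dim,pixel_size Image geometry (default 512 x 512,
#'   101.61/512 um/px).
#' @param red_intensity,cell_intensity Mean intensities of the extracellular
#'   red channel and of cell objects (8-bit scale).
#' @param poisson Apply Poisson shot noise.
#' @param read_noise_sd SD of additive Gaussian read noise.
#' @param quantize Round intensities to 8-bit integers; default (`NULL`)
#'   quantizes exactly when any noise is enabled.
#' @param fov_id,carrier_id,timepoint_min Metadata for the emitted FOV.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list: `fov` (a [ratio_fov()]) and `truth` (list with
#'   `ph_field`, `cell_mask`, `ratio_true`).
#' @export
gen_snarf_fov <- function(ph_field = "constant", mean_ph = 5.9,
                          ph_levels = c(5, 7), cell_density = 0.15,
                          curve = csnarf4_curve(), dim = c(512, 512),
                          pixel_size = 101.61 / 512, red_intensity = 90,
                          cell_intensity = 230, poisson = TRUE,
                          read_noise_sd = 2, quantize = NULL,
                          fov_id = "FOV1", carrier_id = "C1",
                          timepoint_min = 10, seed = NULL) {
  if (cell_density >= 1)
    stop("gen_snarf_fov: cell_density must be < 1 ",
         "(no extracellular pixels would remain)")
  run <- function() {
    field <- if (is.matrix(ph_field)) {
      stopifnot(all(dim(ph_field) == dim))
      ph_field
    } else switch(match.arg(ph_field, c("constant", "two_region", "gradient")),
      constant = matrix(mean_ph, dim[1], dim[2]),
      two_region = {
        f <- matrix(ph_levels[1], dim[1], dim[2])
        f[, (floor(dim[2] / 2) + 1):dim[2]] <- ph_levels[2]
        f
      },
      gradient = matrix(seq(ph_levels[1], ph_levels[2], length.out = dim[2]),
                        dim[1], dim[2], byrow = TRUE))
    if (any(field < curve$domain[1] - 1e-12) ||
        any(field > curve$domain[2] + 1e-12))
      stop("gen_snarf_fov: pH field values must lie within the curve domain")

    ratio_true <- ratio_from_ph(field, curve)
    red0 <- matrix(red_intensity, dim[1], dim[2])
    green0 <- ratio_true * red_intensity

    cell_mask <- draw_ellipses(dim, cell_density)
    if (any(cell_mask)) {
      overlay <- cell_intensity * cell_mask
      # one-pixel smoothed rim outside the cell, full intensity inside
      halo <- cross_mean(overlay)
      green0 <- pmax(green0, overlay, halo)
      red0 <- pmax(red0, overlay, halo)
    }

    noisy <- poisson || read_noise_sd > 0
    qz <- if (is.null(quantize)) noisy else quantize
    green <- apply_noise(green0, poisson, read_noise_sd, qz)
    red <- apply_noise(red0, poisson, read_noise_sd, qz)

    list(fov = ratio_fov(
           intensity_raster(green, pixel_size, "green"),
           intensity_raster(red, pixel_size, "red"),
           fov_id = fov_id, carrier_id = carrier_id,
           timepoint_min = timepoint_min),
         truth = list(ph_field = field, cell_mask = cell_mask,
                      ratio_true = ratio_true))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

top_k_mask <- function(field, k, eligible = NULL) {
  mask <- matrix(FALSE, nrow(field), ncol(field))
  if (k <= 0) return(mask)
  idx <- if (is.null(eligible)) seq_along(field) else which(eligible)
  stopifnot(k <= length(idx))
  v <- field[idx]
  n <- length(v)
  kth <- sort(v, partial = n - k + 1)[n - k + 1]
  sel <- idx[v >= kth]
  if (length(sel) != k)   # ties at the threshold: fall back to a full order
    sel <- idx[order(v, decreasing = TRUE)[seq_len(k)]]
  mask[sel] <- TRUE
  mask
}

#' Generate a lectin z-stack with known per-slice areas
#'
#' Builds a two-channel stack whose true microbial and lectin area
#' fractions per slice match the requested fractions exactly (up to a
#' single-pixel rounding): smooth Gaussian random fields are thresholded at
#' the exact pixel count, giving blob-like morphology with controlled area.
#' The lectin mask is split between the cell area (the requested overlap
#' fraction) and the intercellular space. Intensities are two-mode
#' (background vs. stained) with Poisson and Gaussian read noise.
#'
#' @param microbial_frac,lectin_frac Numeric vectors (one entry per slice,
#'   same length >= 2) of area fractions in [0, 1].
#' @param overlap_frac Image-area fraction where lectin and cells overlap,
#'   per slice; defaults to half the smaller of the two fractions. Must not
#'   exceed either fraction.
#' @param interslice_um Interslice distance in um (default 2).
#' @param dim,pixel_size Image geometry.
#' @param bg_intensity,fg_intensity Background and stained-pixel mean
#'   intensities.
#' @param poisson,read_noise_sd,quantize Noise model, as in
#'   [gen_snarf_fov()].
#' @param blur_sigma Correlation length of the blob fields in pixels
#'   (spacing of the coarse noise grid that is bilinearly interpolated).
#' @param lectin_name,carrier_id,patient_id,treatment Stack metadata.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list: `stack` (a [zstack()]) and `truth` (per-slice true
#'   `cell_mask`/`lectin_mask` lists plus a `report`-style list of true
#'   areas and volumes, including the intercellular split at dilation
#'   radius `truth_dilation_px`).
#' @export
gen_flba_stack <- function(microbial_frac, lectin_frac,
                           overlap_frac = pmin(microbial_frac, lectin_frac) / 2,
                           interslice_um = 2, dim = c(512, 512),
                           pixel_size = 101.61 / 512, bg_intensity = 40,
                           fg_intensity = 200, poisson = TRUE,
                           read_noise_sd = 2, quantize = NULL,
                           blur_sigma = 6, truth_dilation_px = 1,
                           lectin_name = "AAL", carrier_id = "C1",
                           patient_id = NA_character_,
                           treatment = NA_character_, seed = NULL) {
  n <- length(microbial_frac)
  stopifnot(n >= 2, length(lectin_frac) == n, length(overlap_frac) == n,
            all(microbial_frac >= 0), all(microbial_frac <= 1),
            all(lectin_frac >= 0), all(lectin_frac <= 1))
  if (any(overlap_frac > pmin(microbial_frac, lectin_frac) + 1e-12))
    stop("gen_flba_stack: overlap_frac cannot exceed either area fraction")
  npx <- prod(dim)
  run <- function() {
    slices <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      f_cell <- smooth_field(dim, step = blur_sigma)
      f_lect <- smooth_field(dim, step = blur_sigma)
      k_cell <- round(microbial_frac[i] * npx)
      cell <- top_k_mask(f_cell, k_cell)
      k_in <- round(overlap_frac[i] * npx)
      k_out <- round(lectin_frac[i] * npx) - k_in
      lect <- top_k_mask(f_lect, k_in, eligible = cell) |
              top_k_mask(f_lect, max(k_out, 0), eligible = !cell)
      noisy <- poisson || read_noise_sd > 0
      qz <- if (is.null(quantize)) noisy else quantize
      mk_img <- function(mask) {
        base <- matrix(bg_intensity, dim[1], dim[2])
        base[mask] <- fg_intensity
        apply_noise(base, poisson, read_noise_sd, qz)
      }
      slices[[i]] <- list(lectin = mk_img(lect), cells = mk_img(cell))
      masks[[i]] <- list(cell_mask = cell, lectin_mask = lect)
    }
    stk <- zstack(slices, interslice_um = interslice_um,
                  lectin_name = lectin_name, carrier_id = carrier_id,
                  patient_id = patient_id, treatment = treatment,
                  pixel_size = pixel_size)
    truth <- true_biovolumes(masks, interslice_um, pixel_size,
                             truth_dilation_px)
    truth$masks <- masks
    list(stack = stk, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# layer/total volumes computed directly from boolean masks (generator truth)
true_biovolumes <- function(masks, interslice_um, pixel_size, dilation_px) {
  n <- length(masks)
  px2 <- pixel_size^2
  layers <- slice_layers(n)
  per <- do.call(rbind, lapply(seq_len(n), function(i) {
    cell <- masks[[i]]$cell_mask
    lect <- masks[[i]]$lectin_mask
    dil <- dilate_mask(cell, dilation_px)
    data.frame(slice = i, layer = as.character(layers[i]),
               microbial_um2 = sum(cell) * px2,
               lectin_um2 = sum(lect) * px2,
               intercellular_um2 = sum(lect & !dil) * px2)
  }))
  comp <- function(col) {
    v <- vapply(c("bottom", "middle", "top"), function(l)
      sum(per[[col]][per$layer == l]) * interslice_um, numeric(1))
    c(v, total = sum(v))
  }
  list(slices = per,
       microbial_um3 = comp("microbial_um2"),
       lectin_um3 = comp("lectin_um2"),
       intercellular_um3 = comp("intercellular_um2"),
       interslice_um = interslice_um, pixel_size = pixel_size,
       dilation_px = dilation_px)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a paired ASV count table with known effects
#'
#' Emulates a split-mouth paired amplicon table: per-ASV baseline
#' log-abundances (log-normal, giving a realistic skewed community), a
#' patient effect shared by both treatment sides (patient-dominant
#' structure), optional treatment log-fold shifts on a designated ASV
#' subset, per-sample Dirichlet overdispersion, and multinomial sampling at
#' the stated sequencing depth.
#'
#' @param n_patients Number of patients (default 10).
#' @param n_asvs Number of ASVs (default 150).
#' @param depth Sequencing depth per sample (>= 1000; default 20000).
#' @param baseline_sd SD of the log-normal baseline abundances (default 1.5).
#' @param patient_sd SD of the per-patient, per-ASV log effect shared by
#'   both sides (default 2.0, making patient identity the dominant
#'   compositional factor).
#' @param sample_sd SD of independent per-sample log noise (default 0.3,
#'   the residual side-to-side variation within a patient).
#' @param dirichlet_conc Dirichlet concentration for per-sample
#'   overdispersion; `Inf` disables it (default 5000, mild overdispersion
#'   on top of multinomial sampling).
#' @param n_effect Number of designated treatment-shifted ASVs (default 0).
#'   Shifted ASVs are drawn from the abundant part of the community (top
#'   decile of baseline abundances), where paired tests after the
#'   abundance filter can see them.
#' @param effect_log Log-scale shift added to designated ASVs on the ARG
#'   side (scalar or length `n_effect`; positive = up in ARG; default 1.5).
#' @param seed Integer seed.
#' @return A list: `table` (an [asv_table()]) and `truth` (list with
#'   `effect_asvs` indices, `effect_log`, and the generator parameters).
#' @export
gen_asv_table <- function(n_patients = 10, n_asvs = 150, depth = 20000,
                          baseline_sd = 1.5, patient_sd = 2.0,
                          sample_sd = 0.3, dirichlet_conc = 5000,
                          n_effect = 0, effect_log = 1.5, seed = 1) {
  stopifnot(depth >= 1000, n_effect <= n_asvs)
  withr::with_seed(seed, {
    base <- stats::rnorm(n_asvs, 0, baseline_sd)
    eligible <- order(base, decreasing = TRUE)[
      seq_len(max(n_effect, ceiling(0.1 * n_asvs)))]
    effect_asvs <- if (n_effect > 0) sort(sample(eligible, n_effect))
                   else integer(0)
    shift <- rep(0, n_asvs)
    shift[effect_asvs] <- rep_len(effect_log, n_effect)
    counts <- matrix(0L, 2 * n_patients, n_asvs)
    patient_id <- character(2 * n_patients)
    treatment <- character(2 * n_patients)
    row <- 0
    for (p in seq_len(n_patients)) {
      pat_eff <- stats::rnorm(n_asvs, 0, patient_sd)
      for (tr in c("ARG", "NoARG")) {
        row <- row + 1
        lg <- base + pat_eff + stats::rnorm(n_asvs, 0, sample_sd) +
          if (tr == "ARG") shift else 0
        pr <- exp(lg - max(lg))
        pr <- pr / sum(pr)
        if (is.finite(dirichlet_conc))
          pr <- rdirichlet1(dirichlet_conc * pr)
        counts[row, ] <- stats::rmultinom(1, depth, pr)[, 1]
        patient_id[row] <- sprintf("P%02d", p)
        treatment[row] <- tr
      }
    }
    colnames(counts) <- sprintf("ASV%03d", seq_len(n_asvs))
    tab <- asv_table(counts, patient_id, treatment)
    list(table = tab,
         truth = list(effect_asvs = effect_asvs,
                      effect_log = shift[effect_asvs],
                      patient_sd = patient_sd, sample_sd = sample_sd,
                      dirichlet_conc = dirichlet_conc, depth = depth))
  })
}

#' Generate FOV-level pH measurements for a paired cohort
#'
#' Hierarchical Gaussian model of the pH arm of the study, at the summary
#' level (no images): per-timepoint placebo-side mean plus the imposed
#' treatment effect, a patient random effect shared across sides and
#' timepoints, a biofilm random effect per carrier, and FOV-level noise.
#' Defaults mirror the study layout (10 patients, duplicate biofilms per
#' side, 9 FOVs per biofilm, timepoints 10 and 35 min) with imposed
#' treatment effects of +0.19 and +0.16 pH units and the variance
#' components patient 0.3, biofilm 0.1, FOV 0.15 (SD, pH units).
#'
#' @param n_patients,biofilms_per_side,fovs_per_biofilm Layout counts.
#' @param timepoints Timepoints in minutes.
#' @param delta_ph Named vector: imposed ARG - NoARG effect per timepoint.
#' @param noarg_ph Named vector: placebo-side mean pH per timepoint.
#' @param patient_sd,biofilm_sd,fov_sd Variance components (SDs, pH units).
#' @param seed Integer seed.
#' @return A list: `fovs` (data frame `patient_id`, `treatment`,
#'   `carrier_id`, `fov_id`, `timepoint_min`, `mean_ph`, `reportable`) and
#'   `truth` (the imposed effects and the realized per-biofilm means).
#' @export
gen_ph_cohort <- function(n_patients = 10, biofilms_per_side = 2,
                          fovs_per_biofilm = 9, timepoints = c(10, 35),
                          delta_ph = c("10" = 0.19, "35" = 0.16),
                          noarg_ph = c("10" = 5.87, "35" = 5.68),
                          patient_sd = 0.3, biofilm_sd = 0.1, fov_sd = 0.15,
                          seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    biofilm_truth <- list()
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%02d", p)
      pat_eff <- stats::rnorm(1, 0, patient_sd)
      for (tr in c("ARG", "NoARG")) {
        for (b in seq_len(biofilms_per_side)) {
          cid <- sprintf("%s_%s_B%d", pid, tr, b)
          bio_eff <- stats::rnorm(1, 0, biofilm_sd)
          for (tp in timepoints) {
            key <- as.character(tp)
            mu <- noarg_ph[[key]] + pat_eff + bio_eff +
              if (tr == "ARG") delta_ph[[key]] else 0
            ph <- mu + stats::rnorm(fovs_per_biofilm, 0, fov_sd)
            rows[[length(rows) + 1]] <- data.frame(
              patient_id = pid, treatment = tr, carrier_id = cid,
              fov_id = sprintf("FOV%d", seq_len(fovs_per_biofilm)),
              timepoint_min = tp, mean_ph = ph, reportable = TRUE,
              stringsAsFactors = FALSE)
            biofilm_truth[[length(biofilm_truth) + 1]] <- data.frame(
              patient_id = pid, treatment = tr, carrier_id = cid,
              timepoint_min = tp, true_mean_ph = mu,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(fovs = do.call(rbind, rows),
         truth = list(delta_ph = delta_ph, noarg_ph = noarg_ph,
                      biofilms = do.call(rbind, biofilm_truth)))
  })
}

#' Split-mouth treatment allocation by blocked randomization
#'
#' Assigns the treated splint side per patient by random permutation within
#' blocks of 2, so that every consecutive pair of patients contains each
#' allocation order exactly once.
#'
#' @param n_patients Number of patients (even for fully balanced blocks).
#' @param seed Integer seed.
#' @return Data frame: `patient_id`, `arg_side` in `{"left", "right"}`.
#' @export
allocate_split_mouth <- function(n_patients, seed = 1) {
  withr::with_seed(seed, {
    sides <- unlist(lapply(seq_len(ceiling(n_patients / 2)), function(b)
      sample(c("left", "right"))))[seq_len(n_patients)]
    data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
               arg_side = sides, stringsAsFactors = FALSE)
  })
}

#' Cohort specification for the full synthetic study
#'
#' Bundles every generator parameter for [gen_cohort()]. Defaults mirror
#' the study layout: 10 patients, split-mouth allocation in blocks of 2,
#' duplicate pH biofilms per side with 9 laser-marked FOVs each imaged at
#' 10 and 35 min, one biofilm per lectin and side imaged as 6-slice
#' z-stacks, and one paired ASV sample per side.
#'
#' @param n_patients,biofilms_per_side_ph,biofilms_per_lectin,fovs_per_biofilm
#'   Layout counts.
#' @param timepoints,delta_ph,noarg_ph,patient_sd,biofilm_sd,fov_sd pH model
#'   (see [gen_ph_cohort()]).
#' @param dim,pixel_size Image geometry.
#' @param cell_density,red_intensity,cell_intensity,poisson,read_noise_sd
#'   Ratio-image model (see [gen_snarf_fov()]).
#' @param flba List: `interslice_um`, per-slice `microbial_frac`, per-lectin
#'   placebo-side `lectin_frac`, and per-lectin ARG multipliers
#'   (`arg_mult`), emulating the observed patterns (fucose-binding lectin
#'   suppressed throughout; galactose-binding lectin redistributed from
#'   bottom to top).
#' @param asv List of [gen_asv_table()] parameters.
#' @param seed Top-level seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10, biofilms_per_side_ph = 2,
                        biofilms_per_lectin = 1, fovs_per_biofilm = 9,
                        timepoints = c(10, 35),
                        delta_ph = c("10" = 0.19, "35" = 0.16),
                        noarg_ph = c("10" = 5.87, "35" = 5.68),
                        patient_sd = 0.3, biofilm_sd = 0.1, fov_sd = 0.15,
                        dim = c(512, 512), pixel_size = 101.61 / 512,
                        cell_density = 0.15, red_intensity = 90,
                        cell_intensity = 230, poisson = TRUE,
                        read_noise_sd = 2,
                        flba = list(
                          interslice_um = 2,
                          microbial_frac = c(0.40, 0.38, 0.34, 0.30, 0.26, 0.22),
                          lectin_frac = list(
                            "AAL" = c(0.10, 0.10, 0.08, 0.08, 0.06, 0.06),
                            "MNA-G" = c(0.12, 0.12, 0.08, 0.08, 0.05, 0.05)),
                          arg_mult = list(
                            "AAL" = rep(0.5, 6),
                            "MNA-G" = c(0.5, 0.5, 1, 1, 1.4, 1.4))),
                        asv = list(n_asvs = 150, depth = 20000,
                                   baseline_sd = 1.5, patient_sd = 2.0,
                                   sample_sd = 0.5, dirichlet_conc = 200,
                                   n_effect = 5, effect_log = 1.5),
                        seed = 1) {
  spec <- as.list(environment())
  stopifnot(n_patients >= 1, biofilms_per_side_ph >= 1,
            fovs_per_biofilm >= 1, all(dim >= 16),
            patient_sd >= 0, biofilm_sd >= 0, fov_sd >= 0,
            cell_density >= 0, cell_density < 1)
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a full synthetic cohort on disk
#'
#' Writes every input the pipeline consumes: two-channel TIFFs for the
#' ratiometric pH arm (one per FOV and timepoint), multi-page TIFFs for the
#' lectin z-stack arm, CSV manifests for both, the paired ASV count table
#' with sample metadata, the treatment allocation, and a ground-truth JSON
#' bundle. A single top-level seed determines everything through named
#' substreams.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @param curve A [calibration_curve()] used to encode the pH fields.
#' @return `out_dir`, invisibly. Side effects: `ph/` and `flba/` image
#'   directories, `manifest_ph.csv`, `manifest_flba.csv`, `asv_counts.csv`,
#'   `asv_meta.csv`, `allocation.csv`, `curve.json`, `truth.json`.
#' @export
gen_cohort <- function(spec = cohort_spec(), out_dir,
                       curve = csnarf4_curve()) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(file.path(out_dir, "ph"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "flba"), recursive = TRUE,
             showWarnings = FALSE)
  seed <- spec$seed

  alloc <- allocate_split_mouth(spec$n_patients,
                                seed = substream_seed(seed, "alloc"))
  utils::write.csv(alloc, file.path(out_dir, "allocation.csv"),
                   row.names = FALSE)
  write_curve_json(curve, file.path(out_dir, "curve.json"))

  # pH arm: hierarchical biofilm means realized once, then one image per
  # FOV x timepoint with a constant field at the biofilm mean + FOV jitter
  ph_cohort <- gen_ph_cohort(
    n_patients = spec$n_patients,
    biofilms_per_side = spec$biofilms_per_side_ph,
    fovs_per_biofilm = spec$fovs_per_biofilm,
    timepoints = spec$timepoints, delta_ph = spec$delta_ph,
    noarg_ph = spec$noarg_ph, patient_sd = spec$patient_sd,
    biofilm_sd = spec$biofilm_sd, fov_sd = spec$fov_sd,
    seed = substream_seed(seed, "ph"))
  fovs <- ph_cohort$fovs
  fovs$mean_ph <- pmin(pmax(fovs$mean_ph, curve$domain[1] + 0.05),
                       curve$domain[2] - 0.05)
  manifest_ph <- fovs[c("patient_id", "treatment", "carrier_id", "fov_id",
                        "timepoint_min")]
  manifest_ph$path <- sprintf("ph/%s_%s_t%d.tif", fovs$carrier_id,
                              fovs$fov_id, fovs$timepoint_min)
  manifest_ph$true_mean_ph <- fovs$mean_ph
  for (i in seq_len(nrow(fovs))) {
    g <- gen_snarf_fov(
      ph_field = "constant", mean_ph = fovs$mean_ph[i],
      cell_density = spec$cell_density, curve = curve, dim = spec$dim,
      pixel_size = spec$pixel_size, red_intensity = spec$red_intensity,
      cell_intensity = spec$cell_intensity, poisson = spec$poisson,
      read_noise_sd = spec$read_noise_sd,
      fov_id = fovs$fov_id[i], carrier_id = fovs$carrier_id[i],
      timepoint_min = fovs$timepoint_min[i],
      seed = substream_seed(seed, "snarf", fovs$carrier_id[i],
                            fovs$fov_id[i], fovs$timepoint_min[i]))
    write_fov_tiff(g$fov, file.path(out_dir, manifest_ph$path[i]))
  }
  utils::write.csv(manifest_ph[c("patient_id", "treatment", "carrier_id",
                                 "fov_id", "timepoint_min", "path")],
                   file.path(out_dir, "manifest_ph.csv"), row.names = FALSE)

  # FLBA arm
  lectins <- names(spec$flba$lectin_frac)
  flba_rows <- list()
  flba_truth <- list()
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%02d", p)
    for (tr in c("ARG", "NoARG")) {
      for (ln in lectins) {
        for (b in seq_len(spec$biofilms_per_lectin)) {
          for (f in seq_len(spec$fovs_per_biofilm)) {
            lf <- spec$flba$lectin_frac[[ln]] *
              (if (tr == "ARG") spec$flba$arg_mult[[ln]] else 1)
            cid <- sprintf("%s_%s_%s_B%d", pid, tr, ln, b)
            fid <- sprintf("FOV%d", f)
            g <- gen_flba_stack(
              microbial_frac = spec$flba$microbial_frac, lectin_frac = lf,
              interslice_um = spec$flba$interslice_um, dim = spec$dim,
              pixel_size = spec$pixel_size, poisson = spec$poisson,
              read_noise_sd = spec$read_noise_sd, lectin_name = ln,
              carrier_id = cid, patient_id = pid, treatment = tr,
              seed = substream_seed(seed, "flba", cid, fid))
            path <- sprintf("flba/%s_%s.tif", cid, fid)
            write_zstack_tiff(g$stack, file.path(out_dir, path))
            flba_rows[[length(flba_rows) + 1]] <- data.frame(
              patient_id = pid, treatment = tr, lectin = ln,
              carrier_id = cid, fov_id = fid,
              interslice_um = spec$flba$interslice_um, path = path,
              stringsAsFactors = FALSE)
            flba_truth[[length(flba_truth) + 1]] <- data.frame(
              carrier_id = cid, fov_id = fid,
              true_lectin_um3 = g$truth$lectin_um3[["total"]],
              true_microbial_um3 = g$truth$microbial_um3[["total"]],
              true_intercellular_um3 = g$truth$intercellular_um3[["total"]],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  utils::write.csv(do.call(rbind, flba_rows),
                   file.path(out_dir, "manifest_flba.csv"),
                   row.names = FALSE)

  # ASV arm
  asv <- do.call(gen_asv_table,
                 c(list(n_patients = spec$n_patients,
                        seed = substream_seed(seed, "asv")), spec$asv))
  utils::write.csv(data.frame(sample_id = rownames(asv$table$counts),
                              asv$table$counts, check.names = FALSE),
                   file.path(out_dir, "asv_counts.csv"), row.names = FALSE)
  utils::write.csv(asv$table$meta, file.path(out_dir, "asv_meta.csv"),
                   row.names = FALSE)

  truth <- list(
    seed = seed,
    delta_ph = as.list(ph_cohort$truth$delta_ph),
    noarg_ph = as.list(ph_cohort$truth$noarg_ph),
    ph_biofilms = ph_cohort$truth$biofilms,
    ph_fovs = manifest_ph[c("carrier_id", "fov_id", "timepoint_min",
                            "true_mean_ph")],
    flba = do.call(rbind, flba_truth),
    asv_effect_asvs = asv$truth$effect_asvs,
    asv_effect_log = asv$truth$effect_log)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
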