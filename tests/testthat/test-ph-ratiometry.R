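curve <- csnarf4_curve()

full_mask <- function(n) biofilmph:::new_mask(matrix(TRUE, n, n),
                                              "extracellular",
                                              pixel_size = 1)

test_that("ratio maps divide channels only where defined", {
  n <- 24
  g <- make_raster(matrix(120, n, n))
  r <- make_raster(matrix(120, n, n), channel = "red")
  fov <- ratio_fov(g, r)
  rm1 <- ratio_map(fov, full_mask(n))
  expect_true(all(rm1 == 1))
  expect_equal(attr(rm1, "n_valid"), n * n)

  # zero-red pixels become invalid, exactly
  rv <- matrix(120, n, n); rv[1:5, 1] <- 0
  fov2 <- ratio_fov(g, make_raster(rv, channel = "red"))
  rm2 <- ratio_map(fov2, full_mask(n))
  expect_equal(sum(is.na(rm2)), 5)

  # empty extracellular mask: unreportable, not an error
  empty <- biofilmph:::new_mask(matrix(FALSE, n, n), "extracellular",
                                pixel_size = 1)
  rm3 <- ratio_map(fov, empty)
  expect_false(attr(rm3, "reportable"))
  s <- fov_summary(rm3, curve)
  expect_false(s$reportable)
  expect_true(is.na(s$mean_ph))
})

test_that("FOV summaries convert first and average second", {
  n <- 24
  # uniform field at pH 6: round trip is exact
  ratio6 <- matrix(ratio_from_ph(6, curve), n, n)
  s <- fov_summary(ratio6, curve)
  expect_equal(s$mean_ph, 6, tolerance = 1e-12)
  expect_equal(s$sd_ph, 0)
  expect_equal(s$n_pixels, n * n)

  # noiseless two-region field: arithmetic mean of the two pH values
  half <- matrix(ratio_from_ph(5, curve), n, n)
  half[, (n / 2 + 1):n] <- ratio_from_ph(7, curve)
  s2 <- fov_summary(half, curve)
  expect_equal(s2$mean_ph, 6, tolerance = 1e-12)

  # averaging ratios before conversion is NOT the same operation
  ph_of_mean_ratio <- ph_from_ratio(mean(half), curve)
  expect_gt(abs(ph_of_mean_ratio - 6), 0.1)

  # out-of-domain pixels are excluded and their fraction reported
  mix <- matrix(ratio_from_ph(6, curve), n, n)
  mix[1:6, 1] <- ratio_from_ph(9, curve)   # converts to pH 9, out of domain
  s3 <- fov_summary(mix, curve)
  expect_equal(s3$mean_ph, 6, tolerance = 1e-12)
  expect_equal(s3$out_of_domain_fraction, 6 / (n * n))

  # mean is invariant to pixel order and to added invalid pixels
  perm <- matrix(sample(as.numeric(ratio6)), n, n)
  expect_equal(fov_summary(perm, curve)$mean_ph, s$mean_ph)
  with_na <- ratio6; with_na[1:10, 1] <- NA
  expect_equal(fov_summary(with_na, curve)$mean_ph, 6, tolerance = 1e-12)
})

test_that("noiseless synthetic FOVs are recovered pixel-exactly", {
  g <- gen_snarf_fov("gradient", ph_levels = c(5, 7), cell_density = 0.1,
                     poisson = FALSE, read_noise_sd = 0, dim = c(96, 96),
                     pixel_size = 1, seed = 2)
  out <- process_fov(g$fov, curve)
  used <- !is.na(out$ratios)
  ph <- ph_from_ratio(out$ratios[used], curve)
  expect_lt(max(abs(ph - g$truth$ph_field[used])), 1e-9)
  # no used pixel touches the true cell mask
  expect_false(any(used & g$truth$cell_mask))
})

test_that("noisy synthetic FOVs recover the imposed pH within tolerance", {
  g <- gen_snarf_fov("constant", mean_ph = 5.5, cell_density = 0.15,
                     dim = c(256, 256), seed = 7)
  out <- process_fov(g$fov, curve)
  expect_lt(abs(out$summary$mean_ph - 5.5), 0.05)
  expect_lt(abs(sum(out$cell_mask) / sum(g$truth$cell_mask) - 1), 0.03)
})

test_that("biofilm means aggregate FOVs arithmetically", {
  fovs <- data.frame(mean_ph = rep(5.8, 9), reportable = TRUE)
  expect_equal(biofilm_ph(fovs)$mean_ph, 5.8)
  expect_equal(biofilm_ph(fovs)$n_fov, 9)
  fovs2 <- data.frame(mean_ph = seq(5.0, 5.8, by = 0.1), reportable = TRUE)
  expect_equal(biofilm_ph(fovs2)$mean_ph, 5.4)
  expect_error(biofilm_ph(data.frame(mean_ph = NA_real_,
                                     reportable = FALSE)), "reportable")
})

test_that("paired per-patient differences average duplicate biofilms", {
  bio <- data.frame(
    patient_id = "P01", timepoint_min = 10,
    treatment = c("ARG", "ARG", "NoARG", "NoARG"),
    carrier_id = c("a1", "a2", "n1", "n2"),
    mean_ph = c(6.0, 6.2, 5.9, 5.9))
  d <- paired_delta_ph(bio)
  expect_equal(d$delta_ph, 0.2, tolerance = 1e-12)
  expect_equal(d$ph_arg, 6.1)
  expect_equal(d$ph_noarg, 5.9)

  same <- bio; same$mean_ph <- 6
  expect_equal(paired_delta_ph(same)$delta_ph, 0)

  # a patient missing one side is excluded with a message
  solo <- data.frame(patient_id = c("P01", "P01", "P02"),
                     timepoint_min = 10,
                     treatment = c("ARG", "NoARG", "ARG"),
                     carrier_id = c("a", "n", "x"),
                     mean_ph = c(6, 5.9, 6.1))
  expect_message(d2 <- paired_delta_ph(solo), "lacks one treatment side")
  expect_equal(nrow(d2), 1)
  expect_equal(d2$patient_id, "P01")
})

test_that("a summary-level cohort recovers its imposed treatment effect", {
  coh <- gen_ph_cohort(seed = 17)
  bio <- cohort_biofilm_ph(coh$fovs)
  d <- paired_delta_ph(bio)
  d10 <- d[d$timepoint_min == 10, ]
  expect_equal(nrow(d10), 10)
  expect_lt(abs(mean(d10$delta_ph) - 0.19), 0.05)
  d35 <- d[d$timepoint_min == 35, ]
  expect_lt(abs(mean(d35$delta_ph) - 0.16), 0.05)
})
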