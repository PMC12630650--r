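curve <- csnarf4_curve()

test_that("generators are deterministic under a fixed seed", {
  a <- gen_snarf_fov(dim = c(64, 64), seed = 5)
  b <- gen_snarf_fov(dim = c(64, 64), seed = 5)
  expect_identical(a, b)
  mf <- rep(0.3, 6); lf <- rep(0.1, 6)
  expect_identical(gen_flba_stack(mf, lf, dim = c(64, 64), seed = 5),
                   gen_flba_stack(mf, lf, dim = c(64, 64), seed = 5))
  expect_identical(gen_asv_table(seed = 5), gen_asv_table(seed = 5))
  expect_identical(gen_ph_cohort(seed = 5), gen_ph_cohort(seed = 5))
  # different seeds give different draws
  expect_false(identical(gen_ph_cohort(seed = 5), gen_ph_cohort(seed = 6)))
  # substreams are stable and tag-sensitive
  expect_identical(substream_seed(1, "a", 2), substream_seed(1, "a", 2))
  expect_false(substream_seed(1, "a") == substream_seed(1, "b"))
})

test_that("calibration set emits the full titration series", {
  cal <- gen_calibration_set(curve, noise_sd = 0, dim = c(32, 32),
                             n_fov = 3, seed = 1)
  expect_length(cal$images, 21)
  expect_equal(as.numeric(names(cal$images)), seq(4, 8, by = 0.2))
  # noiseless buffers reproduce the forward relation exactly
  tab <- calibration_from_images(cal$images)
  expect_equal(tab$mean_ratio, cal$truth$true_ratio, tolerance = 1e-12)
  expect_true(all(tab$n_fov == 3))
  refit <- fit_calibration(tab)
  expect_lt(abs(refit$a - curve$a), 1e-6)
})

test_that("ratio FOV generator respects its contract", {
  # constant field, no cells, no noise: exact round trip through the
  # summary
  g <- gen_snarf_fov("constant", mean_ph = 6, cell_density = 0,
                     poisson = FALSE, read_noise_sd = 0, dim = c(32, 32),
                     seed = 1)
  full <- biofilmph:::new_mask(matrix(TRUE, 32, 32), "extracellular",
                               pixel_size = 1)
  s <- fov_summary(ratio_map(g$fov, full), curve)
  expect_equal(s$mean_ph, 6, tolerance = 1e-12)
  expect_equal(s$sd_ph, 0)

  # two-region field recovers both regional means (valid in-domain pixels,
  # as the FOV summary uses them)
  g2 <- gen_snarf_fov("two_region", ph_levels = c(5.5, 6.5),
                      cell_density = 0.1, dim = c(128, 128), seed = 3)
  out <- process_fov(g2$fov, curve)
  ph <- ph_from_ratio(out$ratios, curve)
  keep <- !is.na(ph) & ph_in_domain(ph, curve)
  left <- g2$truth$ph_field == 5.5 & keep
  right <- g2$truth$ph_field == 6.5 & keep
  expect_lt(abs(mean(ph[left]) - 5.5), 0.07)
  expect_lt(abs(mean(ph[right]) - 6.5), 0.07)

  expect_error(gen_snarf_fov(cell_density = 1, seed = 1), "cell_density")
  expect_error(gen_snarf_fov("constant", mean_ph = 9, dim = c(32, 32),
                             seed = 1), "domain")
})

test_that("z-stack generator hits requested areas and rejects infeasible overlap", {
  mf <- c(0.4, 0.38, 0.34, 0.3, 0.26, 0.22)
  lf <- c(0.1, 0.1, 0.08, 0.08, 0.06, 0.06)
  g <- gen_flba_stack(mf, lf, dim = c(64, 64), seed = 2)
  npx <- 64 * 64
  for (i in 1:6) {
    expect_lt(abs(sum(g$truth$masks[[i]]$cell_mask) / npx - mf[i]), 0.01)
    expect_lt(abs(sum(g$truth$masks[[i]]$lectin_mask) / npx - lf[i]), 0.01)
  }
  # zero lectin everywhere: pipeline total is exactly zero
  g0 <- gen_flba_stack(mf, rep(0, 6), dim = c(64, 64),
                       poisson = FALSE, read_noise_sd = 0, seed = 2)
  r0 <- stack_biovolumes(g0$stack, method = "fixed", fixed_lectin = 128,
                         fixed_cells = 128)
  expect_equal(unname(r0$lectin_um3[["total"]]), 0)
  expect_error(gen_flba_stack(rep(0.1, 6), rep(0.2, 6),
                              overlap_frac = rep(0.15, 6), seed = 1),
               "overlap")
})

test_that("ASV generator produces a paired patient-dominant table", {
  g <- gen_asv_table(n_patients = 8, n_asvs = 60, depth = 5000,
                     n_effect = 4, seed = 9)
  expect_equal(dim(g$table$counts), c(16, 60))
  expect_true(all(rowSums(g$table$counts) == 5000))
  expect_silent(biofilmph:::check_paired(g$table))
  expect_length(g$truth$effect_asvs, 4)
  # imposed shifts are recovered in sign by the paired pipeline
  da <- paired_differential_abundance(g$table)
  spiked <- sprintf("ASV%03d", g$truth$effect_asvs)
  hit <- da[da$asv %in% spiked, ]
  expect_true(all(hit$clr_effect > 0))
})

test_that("split-mouth allocation is balanced in blocks of two", {
  al <- allocate_split_mouth(10, seed = 3)
  expect_equal(sum(al$arg_side == "left"), 5)
  for (b in 1:5)
    expect_setequal(al$arg_side[c(2 * b - 1, 2 * b)], c("left", "right"))
})

test_that("a small cohort on disk round-trips through the pipeline", {
  spec <- cohort_spec(n_patients = 2, biofilms_per_side_ph = 2,
                      fovs_per_biofilm = 2, dim = c(64, 64),
                      asv = list(n_asvs = 40, depth = 5000, n_effect = 3),
                      seed = 21)
  dir <- withr::local_tempdir()
  gen_cohort(spec, dir)
  expect_true(file.exists(file.path(dir, "manifest_ph.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  out1 <- file.path(dir, "res1")
  res <- run_pipeline(dir, out1)
  expect_equal(nrow(res$delta_ph), 2 * 2)   # patients x timepoints
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  # per-FOV pH recovered close to the imposed values
  merged <- merge(res$fov_ph, truth$ph_fovs,
                  by = c("carrier_id", "fov_id", "timepoint_min"))
  expect_equal(nrow(merged), nrow(res$fov_ph))
  expect_lt(max(abs(merged$mean_ph - merged$true_mean_ph)), 0.1)
  # biovolume rows close to the generator truth
  fl <- res$flba
  tot <- fl[fl$layer == "total" & fl$measure == "lectin_um3", ]
  m2 <- merge(tot, truth$flba, by = c("carrier_id", "fov_id"))
  expect_true(all(abs(m2$value / pmax(m2$true_lectin_um3, 1) - 1) < 0.05))

  # reruns are byte-identical
  out2 <- file.path(dir, "res2")
  run_pipeline(dir, out2)
  for (f in c("fov_ph.csv", "delta_ph.csv", "flba_biovolumes.csv",
              "diff_abundance.csv"))
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
})
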