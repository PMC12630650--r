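# build a deterministic stack from explicit masks (pixel_size 1 => areas in
# pixels), segmented with a fixed threshold of 128
mask_stack <- function(lectin_px, cells_px, n = 32, slices = 6,
                       interslice_um = 2) {
  mk <- function(k, offset = 0) {
    v <- matrix(0, n, n)
    if (k > 0) v[seq_len(k) + offset] <- 200
    v
  }
  zstack(lapply(seq_len(slices), function(i)
    list(lectin = mk(lectin_px), cells = mk(cells_px, offset = n * n / 2))),
    interslice_um = interslice_um, pixel_size = 1)
}

test_that("biovolumes multiply areas by the interslice distance per layer", {
  # 100 px^2 lectin per slice, dz = 2: total 1200, each layer 400
  stk <- mask_stack(lectin_px = 100, cells_px = 150)
  rep <- stack_biovolumes(stk, method = "fixed", fixed_lectin = 128,
                          fixed_cells = 128)
  expect_equal(unname(rep$lectin_um3["total"]), 1200)
  expect_equal(unname(rep$lectin_um3[c("bottom", "middle", "top")]),
               c(400, 400, 400))
  expect_equal(unname(rep$microbial_um3["total"]), 150 * 6 * 2)
  # lectin and cells disjoint here, radius 0: all lectin is intercellular
  rep0 <- stack_biovolumes(stk, method = "fixed", fixed_lectin = 128,
                           fixed_cells = 128, dilation_radius_px = 0)
  expect_equal(rep0$intercellular_um3, rep0$lectin_um3)

  # lectin fully inside cells: intercellular is zero at every layer
  stk2 <- zstack(lapply(1:6, function(i) {
    v <- matrix(0, 32, 32); v[1:50] <- 200
    w <- matrix(0, 32, 32); w[1:100] <- 200
    list(lectin = v, cells = w)
  }), interslice_um = 2, pixel_size = 1)
  rep2 <- stack_biovolumes(stk2, method = "fixed", fixed_lectin = 128,
                           fixed_cells = 128, dilation_radius_px = 0)
  expect_true(all(rep2$intercellular_um3 == 0))

  # a constant channel under Otsu names the slice and channel
  expect_error(stack_biovolumes(mask_stack(0, 10), method = "otsu"),
               "slice 1 lectin")
})

test_that("normalization expresses lectin as percent of microbial volume", {
  stk <- mask_stack(lectin_px = 50, cells_px = 200)
  rep <- normalize_biovolumes(stack_biovolumes(stk, method = "fixed",
                                               fixed_lectin = 128,
                                               fixed_cells = 128))
  expect_equal(unname(rep$normalized$normalized_total_pct["total"]), 25)

  stk0 <- mask_stack(lectin_px = 0, cells_px = 200)
  rep0 <- normalize_biovolumes(stack_biovolumes(stk0, method = "fixed",
                                                fixed_lectin = 128,
                                                fixed_cells = 128))
  expect_equal(unname(rep0$normalized$normalized_total_pct["total"]), 0)

  streq <- mask_stack(lectin_px = 120, cells_px = 120)
  repeq <- normalize_biovolumes(stack_biovolumes(streq, method = "fixed",
                                                 fixed_lectin = 128,
                                                 fixed_cells = 128))
  expect_equal(unname(repeq$normalized$normalized_total_pct["total"]), 100)

  # no microbial signal: undefined, not infinite
  stknone <- mask_stack(lectin_px = 50, cells_px = 0)
  repnone <- normalize_biovolumes(stack_biovolumes(stknone, method = "fixed",
                                                   fixed_lectin = 128,
                                                   fixed_cells = 128))
  expect_true(is.na(repnone$normalized$normalized_total_pct["total"]))
})

test_that("thickness counts occupied slices times the interslice distance", {
  stk <- mask_stack(lectin_px = 10, cells_px = 100, interslice_um = 5)
  expect_equal(thickness(stk, method = "fixed", fixed_cells = 128), 30)

  # only the bottom three slices occupied
  stk3 <- zstack(lapply(1:6, function(i) {
    w <- matrix(0, 32, 32)
    if (i <= 3) w[1:100] <- 200
    list(lectin = matrix(0, 32, 32), cells = w)
  }), interslice_um = 5, pixel_size = 1)
  expect_equal(thickness(stk3, method = "fixed", fixed_cells = 128), 15)

  # occupancy threshold: 2 px of 1024 is below the default 0.5%
  stk_thin <- mask_stack(lectin_px = 0, cells_px = 2, interslice_um = 5)
  expect_equal(thickness(stk_thin, method = "fixed", fixed_cells = 128), 0)
})

test_that("coefficient of variation behaves like SD over mean", {
  expect_equal(fov_variability(c(5, 5, 5)), 0)
  expect_equal(fov_variability(c(4, 6)), sqrt(2) / 5)
  x <- c(2, 3, 7, 4)
  expect_equal(fov_variability(13 * x), fov_variability(x))
  expect_warning(v <- fov_variability(c(-1, 1)), "undefined")
  expect_true(is.na(v))
  expect_error(fov_variability(5), "length")
})

test_that("biovolumes are linear in the interslice distance", {
  mf <- c(0.4, 0.38, 0.34, 0.3, 0.26, 0.22)
  lf <- c(0.1, 0.1, 0.08, 0.08, 0.06, 0.06)
  g1 <- gen_flba_stack(mf, lf, interslice_um = 2, dim = c(64, 64), seed = 4)
  g2 <- gen_flba_stack(mf, lf, interslice_um = 4, dim = c(64, 64), seed = 4)
  r1 <- stack_biovolumes(g1$stack)
  r2 <- stack_biovolumes(g2$stack)
  expect_equal(r2$lectin_um3, 2 * r1$lectin_um3)
  expect_equal(r2$microbial_um3, 2 * r1$microbial_um3)
  expect_equal(r2$intercellular_um3, 2 * r1$intercellular_um3)
})

test_that("a bottom-heavy lectin gradient survives the pipeline", {
  mf <- rep(0.35, 6)
  lf <- c(0.14, 0.14, 0.09, 0.09, 0.04, 0.04)
  g <- gen_flba_stack(mf, lf, dim = c(128, 128), seed = 12)
  rep <- stack_biovolumes(g$stack)
  expect_gt(rep$lectin_um3[["bottom"]], rep$lectin_um3[["middle"]])
  expect_gt(rep$lectin_um3[["middle"]], rep$lectin_um3[["top"]])
  # pipeline agrees with generator truth within 3% on every component
  for (f in c("microbial_um3", "lectin_um3", "intercellular_um3"))
    expect_lt(max(abs(rep[[f]] / g$truth[[f]] - 1)), 0.03)
})
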