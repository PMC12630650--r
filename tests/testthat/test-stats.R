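test_that("clr transform centers each sample's log composition", {
  expect_equal(unname(clr_transform(matrix(1, 1, 4), 0.5)[1, ]), rep(0, 4))
  expect_equal(unname(clr_transform(matrix(c(8, 2), 1), 0)[1, ]),
               c(log(2), -log(2)))
  set.seed(3)
  m <- matrix(rpois(60, 20), 6, 10)
  expect_lt(max(abs(rowSums(clr_transform(m)))), 1e-9)
  # doubling depth with positive counts and no pseudocount changes nothing
  mp <- m + 1
  expect_equal(clr_transform(2 * mp, 0), clr_transform(mp, 0))
  expect_error(clr_transform(matrix(-1, 2, 2)), "non-negative")
  expect_error(clr_transform(matrix(c(0, 1), 1), 0), "positive")
})

test_that("paired Wilcoxon pipeline matches full sign-pattern enumeration", {
  g <- gen_asv_table(n_patients = 10, n_asvs = 30, depth = 5000, seed = 8)
  da <- paired_differential_abundance(g$table)
  clr <- clr_transform(g$table)
  m <- g$table$meta
  ord <- function(tr) vapply(unique(m$patient_id), function(p)
    which(m$patient_id == p & m$treatment == tr), integer(1))
  dmat <- clr[ord("ARG"), , drop = FALSE] - clr[ord("NoARG"), , drop = FALSE]
  checked <- 0
  for (i in seq_len(nrow(da))) {
    d <- dmat[, da$asv[i]]
    if (any(d == 0) || any(duplicated(abs(d)))) next
    expect_equal(da$p[i], enum_signrank_p(d), tolerance = 1e-12)
    expect_equal(da$clr_effect[i], mean(d), tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
  # BH: q >= p, q in [0,1], and q is monotone in p
  expect_true(all(da$q >= da$p - 1e-15))
  expect_true(all(da$q >= 0 & da$q <= 1))
  o <- order(da$p)
  expect_true(all(diff(da$q[o]) >= -1e-15))
})

test_that("degenerate and malformed paired designs are handled", {
  # identical compositions on both sides: zero-variance ASVs report p = 1
  counts <- matrix(rep(c(50, 30, 20, 10, 5), each = 4), 4, 5)
  tab <- asv_table(counts, rep(c("P1", "P2"), each = 2),
                   rep(c("ARG", "NoARG"), 2))
  da <- paired_differential_abundance(tab, min_mean_abundance_pct = 1)
  expect_true(all(da$zero_variance))
  expect_true(all(da$p == 1))
  # an unpaired sample is an error naming the patient
  tab2 <- asv_table(counts[1:3, ], c("P1", "P1", "P2"),
                    c("ARG", "NoARG", "ARG"))
  expect_error(paired_differential_abundance(tab2), "P2")
  expect_error(asv_table(counts, rep("P1", 4), rep("bad", 4)), "treatment")
})

test_that("clr PCA is deterministic and orders variance", {
  g <- gen_asv_table(n_patients = 6, n_asvs = 40, depth = 5000, seed = 4)
  pc <- pca_clr(g$table)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  # sign convention: largest-magnitude loading positive per component
  for (k in 1:3) {
    j <- which.max(abs(pc$loadings[, k]))
    expect_gt(pc$loadings[j, k], 0)
  }
  # duplicated samples score identically
  cnt <- g$table$counts
  cnt[2, ] <- cnt[1, ]
  tab <- asv_table(cnt, g$table$meta$patient_id, g$table$meta$treatment)
  pc2 <- pca_clr(tab)
  expect_equal(unname(pc2$scores[1, ]), unname(pc2$scores[2, ]))
  expect_error(pca_clr(matrix(1:4, 2, 2)), "3 samples")
})

test_that("mixed model recovers a known treatment effect", {
  # zero noise: the difference is exact and both estimators agree
  coh0 <- gen_ph_cohort(patient_sd = 0, biofilm_sd = 0, fov_sd = 0,
                        delta_ph = c("10" = 0.2, "35" = 0.2),
                        noarg_ph = c("10" = 5.8, "35" = 5.8), seed = 1)
  d0 <- coh0$fovs[coh0$fovs$timepoint_min == 10, ]
  dat0 <- data.frame(value = d0$mean_ph, group = d0$treatment,
                     patient = d0$patient_id, biofilm = d0$carrier_id)
  h0 <- suppressMessages(suppressWarnings(hierarchical_estimate(dat0)))
  expect_equal(abs(h0$difference), 0.2, tolerance = 1e-9)
  expect_equal(sort(h0$group_means$mean), c(5.8, 6.0), tolerance = 1e-9)

  # realistic variance components: estimate within 0.1 of truth, both
  # estimators agree in sign
  coh <- gen_ph_cohort(seed = 23)
  d <- coh$fovs[coh$fovs$timepoint_min == 10, ]
  dat <- data.frame(value = d$mean_ph, group = d$treatment,
                    patient = d$patient_id, biofilm = d$carrier_id)
  h <- hierarchical_estimate(dat)
  expect_equal(h$method, "lmm")
  expect_lt(abs(abs(h$difference) - 0.19), 0.1)
  ts <- two_stage_estimate(dat)
  expect_equal(sign(ts$difference), sign(h$difference))
  expect_lt(abs(ts$difference - h$difference), 0.05)

  # degenerate design (one FOV, one biofilm per cell) falls back
  dg <- expand.grid(patient = sprintf("P%d", 1:6),
                    group = c("ARG", "NoARG"))
  dg$biofilm <- "B1"
  set.seed(2)
  dg$value <- 6 + 0.1 * (dg$group == "ARG") + rnorm(nrow(dg), 0, 0.1)
  expect_warning(hf <- hierarchical_estimate(dg), "two-stage")
  expect_equal(hf$method, "two_stage")
  # ... and then equals the paired t on patient values exactly
  w <- reshape(stats::aggregate(value ~ patient + group, dg, mean),
               idvar = "patient", timevar = "group", direction = "wide")
  tt <- paired_t(w$value.NoARG, w$value.ARG)
  expect_equal(hf$p, tt$p, tolerance = 1e-12)
  expect_equal(hf$difference, tt$mean_diff, tolerance = 1e-12)
})

test_that("paired t-test handles exact and textbook cases", {
  r <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(r$exact)
  expect_equal(r$p, 1)
  expect_equal(r$mean_diff, 0)

  # constant non-zero differences: flagged exact, certain difference
  r2 <- paired_t(c(1, 2, 3), c(2, 3, 4))
  expect_true(r2$exact)
  expect_equal(r2$mean_diff, -1)
  expect_equal(r2$p, 0)

  # closed form check against the textbook statistic
  set.seed(31)
  a <- rnorm(12, 6.05, 0.3)
  b <- rnorm(12, 5.87, 0.3)
  r3 <- paired_t(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(12))
  expect_equal(r3$t, t_manual, tolerance = 1e-12)
  expect_equal(r3$p, 2 * pt(-abs(t_manual), 11), tolerance = 1e-12)
  expect_error(paired_t(1, 1), "2 complete pairs")
})

test_that("simple regression returns OLS slope inference", {
  x <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(regress(x, 2 * x))  # perfect fit warns in summary.lm
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_error(regress(rep(1, 5), x), "constant")
  expect_error(regress(1:2, 1:2), "3 points")
  set.seed(5)
  r2 <- regress(rnorm(10), rnorm(10))
  expect_true(r2$p > 0 && r2$p <= 1)
})

test_that("paired sample size follows the normal approximation", {
  # delta equal to the SD
  expect_equal(sample_size_paired(1, 1), 8L)
  # the in vitro hydrogen-ion inputs under the default two-sided convention
  expect_equal(sample_size_paired(1.03e-7, 1.39e-7), 15L)
  # monotone: stricter alpha cannot reduce n
  expect_gte(sample_size_paired(1, 1, alpha = 0.01),
             sample_size_paired(1, 1, alpha = 0.05))
  # one-sided convention is smaller
  expect_lte(sample_size_paired(1, 1, sides = 1), 8L)
  expect_error(sample_size_paired(0, 1), "non-zero")
})
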