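#' Construct a paired ASV count table
#'
#' Amplicon sequence variant (ASV) counts for a split-mouth cohort: one
#' sample per patient and treatment side, with taxonomy labels per ASV.
#'
#' @param counts Non-negative integer matrix, samples in rows, ASVs in
#'   columns (column names are ASV ids).
#' @param patient_id Character/factor vector, one entry per sample row.
#' @param treatment Vector in `{"ARG", "NoARG"}`, one entry per sample row.
#' @param taxonomy Optional character vector of taxonomy labels per ASV.
#' @return An object of class `asv_table`: list with `counts`, `meta`
#'   (data frame `sample_id`, `patient_id`, `treatment`), `taxonomy`.
#' @export
asv_table <- function(counts, patient_id, treatment, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("asv_table: counts must be non-negative")
  stopifnot(length(patient_id) == nrow(counts),
            length(treatment) == nrow(counts))
  if (!all(treatment %in% c("ARG", "NoARG")))
    stop("asv_table: treatment must be 'ARG' or 'NoARG'")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("ASV%d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0(patient_id, "_", treatment)
  if (!is.null(taxonomy)) stopifnot(length(taxonomy) == ncol(counts))
  structure(list(counts = counts,
                 meta = data.frame(sample_id = rownames(counts),
                                   patient_id = as.character(patient_id),
                                   treatment = as.character(treatment),
                                   stringsAsFactors = FALSE),
                 taxonomy = taxonomy),
            class = "asv_table")
}

check_paired <- function(table) {
  m <- table$meta
  for (p in unique(m$patient_id)) {
    tr <- m$treatment[m$patient_id == p]
    if (sum(tr == "ARG") != 1 || sum(tr == "NoARG") != 1)
      stop("paired design incomplete for patient ", p,
           " (need exactly one ARG and one NoARG sample)")
  }
  invisible(TRUE)
}

#' Centered log-ratio transform of count data
#'
#' Per sample (row): log(count + pseudocount) minus the mean of the logged
#' row, i.e. the log ratio to the sample's geometric mean. Each transformed
#' row sums to zero, removing the arbitrary sequencing-depth scale of
#' compositional count data.
#'
#' @param counts Matrix (samples x ASVs) or an [asv_table()].
#' @param pseudocount Positive offset added before the log; `0` is allowed
#'   only when all counts are positive. Note the transform is exactly
#'   depth-invariant only when the pseudocount is negligible against the
#'   counts (or scales with depth).
#' @return Numeric matrix of clr values, same dimensions as the counts.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  if (inherits(counts, "asv_table")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("clr_transform: counts must be non-negative")
  if (pseudocount < 0) stop("clr_transform: pseudocount must be >= 0")
  if (pseudocount == 0 && any(counts == 0))
    stop("clr_transform: pseudocount 0 requires strictly positive counts")
  lg <- log(counts + pseudocount)
  lg - rowMeans(lg)
}

#' Paired differential abundance: Wilcoxon signed-rank on clr counts
#'
#' For every ASV passing the mean relative-abundance filter, tests the
#' within-patient clr differences (ARG minus NoARG) with the Wilcoxon
#' signed-rank test (zero differences dropped; exact null distribution for
#' n <= 25 untied pairs, normal approximation with continuity correction
#' otherwise), then adjusts p-values across the tested ASVs with the
#' Benjamini-Hochberg procedure. The clr transform is computed on the full
#' composition before any filtering; the filter only selects which ASVs are
#' tested (and therefore enters the multiple-testing correction).
#'
#' @param table An [asv_table()] with a complete paired design.
#' @param min_mean_abundance_pct Abundance filter: an ASV is tested when the
#'   mean of its two group mean relative abundances is at least this many
#'   percent (default 1, the conventional display cutoff).
#' @param pseudocount Passed to [clr_transform()].
#' @return A data frame of class `diff_abundance`, one row per tested ASV:
#'   `asv`, `taxonomy`, `mean_ra_arg` / `mean_ra_noarg` (group mean relative
#'   abundances, %), `clr_effect` (mean paired clr difference, ARG - NoARG),
#'   `log2fc` (log2 of NoARG over ARG mean relative abundance; positive =
#'   more abundant under placebo), `statistic` (signed-rank V), `p`, `q`
#'   (BH-adjusted), `zero_variance`. Attribute `excluded_asvs` lists ASVs
#'   with all-zero counts; attribute `filtered_asvs` those below the
#'   abundance filter.
#' @export
paired_differential_abundance <- function(table, min_mean_abundance_pct = 1,
                                          pseudocount = 0.5) {
  stopifnot(inherits(table, "asv_table"))
  check_paired(table)
  m <- table$meta
  counts <- table$counts
  patients <- unique(m$patient_id)
  i_arg <- vapply(patients, function(p)
    which(m$patient_id == p & m$treatment == "ARG"), integer(1))
  i_noarg <- vapply(patients, function(p)
    which(m$patient_id == p & m$treatment == "NoARG"), integer(1))

  all_zero <- colSums(counts) == 0
  rel <- 100 * counts / rowSums(counts)
  mean_arg <- colMeans(rel[i_arg, , drop = FALSE])
  mean_noarg <- colMeans(rel[i_noarg, , drop = FALSE])
  pass <- !all_zero &
    (mean_arg + mean_noarg) / 2 >= min_mean_abundance_pct
  if (!any(pass))
    stop("paired_differential_abundance: no ASV passes the abundance filter")

  clr <- clr_transform(counts, pseudocount)
  d_mat <- clr[i_arg, , drop = FALSE] - clr[i_noarg, , drop = FALSE]

  idx <- which(pass)
  rows <- lapply(idx, function(j) {
    d <- d_mat[, j]
    dz <- d[d != 0]
    if (length(dz) == 0) {
      v <- NA_real_; p <- 1; zv <- TRUE
    } else {
      exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
      wt <- suppressWarnings(
        stats::wilcox.test(dz, exact = exact, correct = TRUE))
      v <- unname(wt$statistic); p <- wt$p.value; zv <- FALSE
    }
    data.frame(
      asv = colnames(counts)[j],
      taxonomy = if (!is.null(table$taxonomy)) table$taxonomy[j]
                 else NA_character_,
      mean_ra_arg = mean_arg[j], mean_ra_noarg = mean_noarg[j],
      clr_effect = mean(d),
      log2fc = log2(mean_noarg[j] / mean_arg[j]),
      statistic = v, p = p, zero_variance = zv,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "excluded_asvs") <- colnames(counts)[all_zero]
  attr(out, "filtered_asvs") <- colnames(counts)[!pass & !all_zero]
  class(out) <- c("diff_abundance", "data.frame")
  out
}

#' PCA of clr-transformed counts
#'
#' Centered (unscaled) principal component analysis of the clr matrix.
#' Component signs are fixed deterministically: each component is flipped,
#' if needed, so that its largest-magnitude loading is positive.
#'
#' @param table An [asv_table()] or counts matrix (>= 3 samples).
#' @param pseudocount Passed to [clr_transform()].
#' @return A list of class `pca_clr`: `scores` (samples x components),
#'   `loadings`, `var_explained` (proportion per component, non-increasing),
#'   `sdev`, and `meta` when available.
#' @export
pca_clr <- function(table, pseudocount = 0.5) {
  meta <- if (inherits(table, "asv_table")) table$meta else NULL
  clr <- clr_transform(table, pseudocount)
  if (nrow(clr) < 3) stop("pca_clr: at least 3 samples are required")
  pc <- stats::prcomp(clr, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev, meta = meta),
            class = "pca_clr")
}

#' Hierarchical (mixed-effects) estimate of a treatment effect
#'
#' Fits a linear mixed-effects model with a fixed treatment effect and
#' random intercepts for patient and biofilm-within-patient, honoring the
#' nesting of fields of view within biofilms within patients. Group means
#' and 95% confidence intervals come from the fitted model (via
#' [emmeans::emmeans()]); the group-difference p-value uses Satterthwaite
#' degrees of freedom. When the design is degenerate for a mixed model
#' (no replication within biofilms or within patient-side cells) or the fit
#' fails, the function falls back, with a warning, to a two-stage
#' aggregation estimator ([two_stage_estimate()]).
#'
#' @param data Data frame with columns `value`, `group` (two levels),
#'   `patient`, `biofilm`.
#' @param reml Use REML (default) or ML variance components.
#' @return A list of class `hier_estimate`: `method` (`"lmm"` or
#'   `"two_stage"`), `group_means` (data frame `group`, `mean`, `lo`, `hi`),
#'   `difference` (second level minus first, alphabetical), `ci`, `p`,
#'   and the underlying `fit`.
#' @export
hierarchical_estimate <- function(data, reml = TRUE) {
  stopifnot(all(c("value", "group", "patient", "biofilm") %in% names(data)))
  data <- data.frame(value = data$value,
                     group = factor(data$group),
                     patient = factor(data$patient),
                     biofilm = factor(paste(data$patient, data$group,
                                            data$biofilm, sep = ":")))
  if (nlevels(data$group) != 2)
    stop("hierarchical_estimate: exactly two groups are required")
  n_pat_both <- sum(vapply(split(data$group, data$patient),
                           function(g) nlevels(droplevels(g)) == 2,
                           logical(1)))
  if (n_pat_both < 2)
    stop("hierarchical_estimate: need >= 2 patients observed in both groups")

  fov_per_biofilm <- tabulate(data$biofilm)
  cells <- interaction(data$patient, data$group, drop = TRUE)
  biofilms_per_cell <- vapply(split(data$biofilm, cells), function(b)
    length(unique(b)), integer(1))
  degenerate <- all(fov_per_biofilm <= 1) && all(biofilms_per_cell <= 1)

  if (!degenerate) {
    fit <- tryCatch(
      lmerTest::lmer(value ~ group + (1 | patient) + (1 | biofilm),
                     data = data, REML = reml),
      error = function(e) NULL)
    if (!is.null(fit)) {
      em <- as.data.frame(emmeans::emmeans(fit, "group"))
      co <- stats::coef(summary(fit))
      est <- co[2, "Estimate"]
      se <- co[2, "Std. Error"]
      df <- co[2, "df"]
      return(structure(list(
        method = "lmm",
        group_means = data.frame(group = as.character(em$group),
                                 mean = em$emmean, lo = em$lower.CL,
                                 hi = em$upper.CL),
        difference = est,
        ci = est + c(-1, 1) * stats::qt(0.975, df) * se,
        p = co[2, "Pr(>|t|)"], fit = fit), class = "hier_estimate"))
    }
  }
  warning("hierarchical_estimate: degenerate design or failed fit; ",
          "falling back to two-stage aggregation")
  two_stage_estimate(data)
}

#' Two-stage aggregation estimate of a treatment effect
#'
#' Averages fields of view to biofilm means, biofilm means to one value per
#' patient and group, then compares the patient-level pairs with a paired
#' t-test. A transparent fallback for [hierarchical_estimate()] that agrees
#' with it in sign on balanced data.
#'
#' @param data Data frame with columns `value`, `group`, `patient`,
#'   `biofilm`.
#' @return A list of class `hier_estimate` with `method = "two_stage"`.
#' @export
two_stage_estimate <- function(data) {
  stopifnot(all(c("value", "group", "patient", "biofilm") %in% names(data)))
  data$group <- factor(data$group)
  lv <- levels(data$group)
  bf <- stats::aggregate(value ~ patient + group + biofilm, data = data,
                         FUN = mean)
  pat <- stats::aggregate(value ~ patient + group, data = bf, FUN = mean)
  w <- stats::reshape(pat, idvar = "patient", timevar = "group",
                      direction = "wide")
  a <- w[[paste0("value.", lv[2])]]
  b <- w[[paste0("value.", lv[1])]]
  keep <- !is.na(a) & !is.na(b)
  tt <- paired_t(a[keep], b[keep])
  d <- a[keep] - b[keep]
  n <- length(d)
  ci <- if (tt$exact) rep(mean(d), 2) else
    mean(d) + c(-1, 1) * stats::qt(0.975, n - 1) * stats::sd(d) / sqrt(n)
  gm <- stats::aggregate(value ~ group, data = pat, FUN = mean)
  sdm <- stats::aggregate(value ~ group, data = pat, FUN = stats::sd)
  half <- stats::qt(0.975, n - 1) * sdm$value / sqrt(n)
  structure(list(
    method = "two_stage",
    group_means = data.frame(group = as.character(gm$group),
                             mean = gm$value,
                             lo = gm$value - half, hi = gm$value + half),
    difference = tt$mean_diff, ci = ci, p = tt$p, fit = tt),
    class = "hier_estimate")
}

#' Paired t-test with a zero-variance guard
#'
#' Classical two-sided paired t-test. When all within-pair differences are
#' identical (zero variance) the t statistic is undefined; the comparison is
#' then flagged `exact` and the p-value is 1 when the common difference is
#' zero and 0 otherwise.
#'
#' @param a,b Numeric vectors, one value per patient, aligned; >= 2 complete
#'   pairs.
#' @return List: `t`, `df`, `p`, `mean_diff` (a - b), `n`, `exact`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("paired_t: need at least 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), n = length(d), exact = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), n = length(d), exact = FALSE)
}

#' Simple linear regression at the patient level
#'
#' Ordinary least squares of y on x with a two-sided test of the slope.
#'
#' @param x,y Numeric vectors, one value per patient; >= 3 points, x not
#'   constant.
#' @return List: `slope`, `intercept`, `p` (slope), `r_squared`, `fit`.
#' @export
regress <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("regress: need at least 3 points")
  if (stats::sd(x) == 0) stop("regress: x is constant")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = s$coefficients[2, 4], r_squared = s$r.squared, fit = fit)
}

#' Paired sample size by the normal approximation
#'
#' n = ceil(((z_{1-alpha/sides} + z_{1-beta}) * sd / mean_diff)^2), the
#' standard normal-approximation sample size for a one-sample (paired
#' difference) comparison.
#'
#' @param mean_diff Expected mean paired difference (non-zero), in the units
#'   of the measurement (e.g. mol/L hydrogen ion concentration).
#' @param sd SD of the paired differences, same units (> 0).
#' @param alpha Type-I error (default 0.05).
#' @param beta Type-II error (default 0.20, i.e. 80% power).
#' @param sides 2 (default) for a two-sided test, 1 for one-sided.
#' @return Integer sample size.
#' @export
sample_size_paired <- function(mean_diff, sd, alpha = 0.05, beta = 0.20,
                               sides = 2) {
  if (mean_diff == 0) stop("sample_size_paired: mean_diff must be non-zero")
  stopifnot(sd > 0, alpha > 0, alpha < 1, beta > 0, beta < 1,
            sides %in% c(1, 2))
  z <- stats::qnorm(1 - alpha / sides) + stats::qnorm(1 - beta)
  as.integer(ceiling((z * sd / abs(mean_diff))^2))
}
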