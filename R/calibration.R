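#' Construct a ratio-pH calibration curve
#'
#' A four-parameter log-logistic relation between the green/red fluorescence
#' emission ratio of a ratiometric pH dye and pH. The curve is parameterized
#' in its monotone forward form
#' \deqn{r(pH) = d + \frac{a}{1 + pH^b / c}}
#' so that the conversion used on images,
#' \deqn{pH(r) = \left(\left(\frac{a}{r - d} - 1\right) \times c\right)^{1/b},}
#' is its exact algebraic inverse. `a` is the ratio amplitude (the dynamic
#' range of the dye), `d` the ratio offset (high-pH asymptote), `b` the Hill
#' exponent governing steepness, and `c` the scale constant; the half-point
#' of the curve sits at pH = c^(1/b).
#'
#' @param a Amplitude, fluorescence-ratio units. Must be > 0.
#' @param d Offset, fluorescence-ratio units.
#' @param c Scale constant (pH^b units). Must be > 0.
#' @param b Exponent (dimensionless). Must be > 0.
#' @param domain Numeric length-2, the pH interval over which the calibration
#'   is supported (buffers were titrated over this range).
#' @return An object of class `calibration_curve`.
#' @seealso [csnarf4_curve()] for the published C-SNARF-4 constants,
#'   [ph_from_ratio()], [ratio_from_ph()], [fit_calibration()].
#' @export
calibration_curve <- function(a, d, c, b, domain = c(4, 8)) {
  stopifnot(is.numeric(a), is.numeric(d), is.numeric(c), is.numeric(b),
            length(a) == 1, length(d) == 1, length(c) == 1, length(b) == 1,
            length(domain) == 2)
  if (!(a > 0 && c > 0 && b > 0))
    stop("calibration_curve: 'a', 'c' and 'b' must all be positive")
  if (!(domain[1] < domain[2]))
    stop("calibration_curve: domain_lo must be smaller than domain_hi")
  structure(list(a = a, d = d, c = c, b = b, domain = as.numeric(domain)),
            class = "calibration_curve")
}

#' The C-SNARF-4 calibration curve
#'
#' The calibration constants for C-SNARF-4 in MES buffers titrated from
#' pH 4.0 to 8.0 in 0.2-unit steps: amplitude 2.249, offset 0.171, scale
#' 136 911 185 393, exponent 14.53178. The half-point of this curve is at
#' pH 5.8392, inside the dye's sensitive range.
#'
#' @return A `calibration_curve`.
#' @export
csnarf4_curve <- function() {
  calibration_curve(a = 2.249, d = 0.171, c = 136911185393, b = 14.53178,
                    domain = c(4, 8))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve: r = %.4g + %.4g / (1 + pH^%.5g / %.6g)\n",
    x$d, x$a, x$b, x$c))
  cat(sprintf("  pH domain [%.2f, %.2f]; half-point pH %.4f\n",
              x$domain[1], x$domain[2], x$c^(1 / x$b)))
  invisible(x)
}

#' Convert fluorescence ratios to pH
#'
#' Applies the inverse calibration relation pixel-wise. Ratios at or below
#' the offset `d`, or at or above `d + a`, have no pre-image on the curve and
#' map to `NA` (invalid). Values that convert to a pH outside the curve's
#' calibrated domain are returned unchanged but can be identified with
#' [ph_in_domain()]; downstream summaries exclude them and report their
#' fraction rather than clamping.
#'
#' @param r Numeric vector (or matrix) of green/red fluorescence ratios.
#' @param curve A [calibration_curve()].
#' @return Numeric of the same shape as `r`: pH values, `NA` where the ratio
#'   is outside the invertible range (r <= d or r >= d + a).
#' @export
ph_from_ratio <- function(r, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  ph <- r
  ph[] <- NA_real_
  ok <- !is.na(r) & r > curve$d & r < curve$d + curve$a
  ph[ok] <- ((curve$a / (r[ok] - curve$d) - 1) * curve$c)^(1 / curve$b)
  # boundary r = d + a gives argument 0 -> pH 0 exactly
  at_hi <- !is.na(r) & r == curve$d + curve$a
  ph[at_hi] <- 0
  ph
}

#' Flag pH values inside the calibrated domain
#'
#' @param ph Numeric pH values (e.g. from [ph_from_ratio()]).
#' @param curve A [calibration_curve()].
#' @return Logical of the same shape: `TRUE` where the value is a number
#'   within `[domain_lo, domain_hi]`, `FALSE` where it is out of domain,
#'   `NA` where the value is invalid.
#' @export
ph_in_domain <- function(ph, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- ph >= curve$domain[1] & ph <= curve$domain[2]
  out
}

#' Convert pH to fluorescence ratio (forward calibration relation)
#'
#' The monotone forward form of the calibration curve, used by the
#' synthetic-image generators and by [fit_calibration()]. Strictly
#' decreasing in pH; tends to `d + a` as pH -> 0 and to `d` as pH grows.
#'
#' @param x Numeric vector (or matrix) of pH values; must be positive.
#' @param curve A [calibration_curve()].
#' @return Fluorescence ratios, same shape as `x`.
#' @export
ratio_from_ph <- function(x, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.na(x) & x <= 0))
    stop("ratio_from_ph: pH values must be positive (root undefined at 0)")
  curve$d + curve$a / (1 + x^curve$b / curve$c)
}

#' Construct a calibration table
#'
#' One row per buffer pH level: the mean and SD of the per-pixel green/red
#' ratio over all pixels of all fields of view imaged for that buffer.
#'
#' @param ph Numeric vector of buffer pH values (unique).
#' @param mean_ratio Mean fluorescence ratio per level (> 0).
#' @param sd_ratio SD of the per-pixel ratios per level.
#' @param n_fov Number of fields of view imaged per level (>= 1).
#' @return A data frame of class `calibration_table`, sorted by pH.
#' @export
calibration_table <- function(ph, mean_ratio, sd_ratio = NA_real_, n_fov = 1L) {
  stopifnot(is.numeric(ph), is.numeric(mean_ratio))
  if (anyDuplicated(ph)) stop("calibration_table: pH values must be unique")
  if (any(mean_ratio <= 0)) stop("calibration_table: mean_ratio must be > 0")
  if (any(n_fov < 1)) stop("calibration_table: n_fov must be >= 1")
  tab <- data.frame(ph = ph, mean_ratio = mean_ratio,
                    sd_ratio = rep_len(sd_ratio, length(ph)),
                    n_fov = as.integer(rep_len(n_fov, length(ph))))
  tab <- tab[order(tab$ph), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("calibration_table", "data.frame")
  tab
}

#' Fit the four-parameter calibration curve to a calibration table
#'
#' Deterministic least-squares fit of r(pH) = d + a / (1 + pH^b / c) to the
#' (pH, mean ratio) pairs of a calibration table, by Levenberg-Marquardt with
#' the scale constant estimated on the log scale for conditioning.
#' Initialization is deterministic (no random restarts): d starts at the
#' minimum observed ratio, a at the observed ratio range, b at 10, and c at
#' midpoint_pH^b.
#'
#' @param table A [calibration_table()] (or data frame with columns `ph` and
#'   `mean_ratio`) with at least 5 distinct pH levels.
#' @param init Optional `calibration_curve` supplying starting values.
#' @return A fitted [calibration_curve()] whose domain is the pH range of the
#'   table, with attribute `fit_report`: a list with residuals, residual sum
#'   of squares, convergence info, and a `monotone_data` flag (a warning is
#'   issued when the observed mean ratios are not decreasing in pH beyond
#'   a small tolerance).
#' @export
fit_calibration <- function(table, init = NULL) {
  stopifnot(is.data.frame(table), all(c("ph", "mean_ratio") %in% names(table)))
  tab <- table[order(table$ph), , drop = FALSE]
  if (length(unique(tab$ph)) < 5)
    stop("fit_calibration: at least 5 distinct pH levels are required ",
         "(4 free parameters)")
  ph <- tab$ph
  r <- tab$mean_ratio

  monotone <- all(diff(r) <= 1e-6 * max(abs(r)))
  if (!monotone)
    warning("fit_calibration: mean ratios are not monotonically decreasing ",
            "in pH; recorded in the fit report")

  if (is.null(init)) {
    mid <- mean(range(ph))
    start <- list(a = diff(range(r)), d = min(r), b = 10, lc = 10 * log(mid))
  } else {
    stopifnot(inherits(init, "calibration_curve"))
    start <- list(a = init$a, d = init$d, b = init$b, lc = log(init$c))
  }

  fit <- minpack.lm::nlsLM(
    r ~ d0 + a0 / (1 + ph^b0 / exp(lc0)),
    start = list(a0 = start$a, d0 = start$d, b0 = start$b, lc0 = start$lc),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  co <- stats::coef(fit)
  curve <- calibration_curve(a = unname(co["a0"]), d = unname(co["d0"]),
                             c = exp(unname(co["lc0"])), b = unname(co["b0"]),
                             domain = range(ph))
  attr(curve, "fit_report") <- list(
    residuals = unname(stats::residuals(fit)),
    rss = sum(stats::residuals(fit)^2),
    monotone_data = monotone,
    n_levels = length(ph),
    converged = fit$convInfo$isConv %||% TRUE)
  curve
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build a calibration table from buffer image sets
#'
#' For each buffer pH level, pools the per-pixel green/red ratios over all
#' pixels of all fields of view imaged for that buffer (buffer solutions are
#' cell-free, so no segmentation mask is applied) and records their mean and
#' SD. Pixels with zero red intensity are excluded; if more than half of a
#' level's pixels are excluded the level is considered unusable and an error
#' is raised.
#'
#' @param images A named list, one element per buffer; names are the buffer
#'   pH values. Each element is a list of [ratio_fov()] objects (at least
#'   one per buffer).
#' @return A [calibration_table()].
#' @export
calibration_from_images <- function(images) {
  if (length(images) == 0) stop("calibration_from_images: no images supplied")
  ph <- as.numeric(names(images))
  if (any(is.na(ph)))
    stop("calibration_from_images: list names must be numeric buffer pH values")
  rows <- lapply(seq_along(images), function(i) {
    fovs <- images[[i]]
    if (length(fovs) == 0)
      stop("calibration_from_images: no FOVs for buffer pH ", ph[i])
    ratios <- unlist(lapply(fovs, function(fov) {
      stopifnot(inherits(fov, "ratio_fov"))
      g <- as.numeric(fov$green)
      rd <- as.numeric(fov$red)
      g[rd > 0] / rd[rd > 0]
    }), use.names = FALSE)
    n_total <- sum(vapply(fovs, function(fov) length(fov$red), numeric(1)))
    if (length(ratios) < 0.5 * n_total)
      stop("calibration_from_images: more than 50% of pixels excluded ",
           "(zero red intensity) at buffer pH ", ph[i])
    data.frame(ph = ph[i], mean_ratio = mean(ratios),
               sd_ratio = stats::sd(ratios), n_fov = length(fovs))
  })
  out <- do.call(rbind, rows)
  calibration_table(out$ph, out$mean_ratio, out$sd_ratio, out$n_fov)
}

#' Serialize / restore a calibration curve as JSON
#'
#' @param curve A [calibration_curve()].
#' @param path File path.
#' @return `write_curve_json` returns `path` invisibly; `read_curve_json`
#'   returns a `calibration_curve`.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(
    list(a = curve$a, d = curve$d, c = curve$c, b = curve$b,
         domain = curve$domain),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(a = x$a, d = x$d, c = x$c, b = x$b, domain = x$domain)
}
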