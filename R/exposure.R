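#' Sampling and analysis parameters
#'
#' The five quantities that set the analytical sensitivity of a filter
#' analysis.
#'
#' @param a_effect_mm2 Effective total filter area, mm^2 (about 385 for a
#'   25 mm filter).
#' @param a_fov_mm2 Area of one field of view, mm^2 (about 0.0031 for a
#'   64 x 48 um field at 2000X).
#' @param n_fov Number of fields of view analyzed (integer >= 1).
#' @param flow_ccm Air flow rate, cm^3/min.
#' @param duration_min Sampling time, minutes.
#' @param confidence Confidence level for intervals (default 0.95).
#' @return An object of class `"sampling_params"`.
#' @export
sampling_params <- function(a_effect_mm2, a_fov_mm2, n_fov, flow_ccm,
                            duration_min, confidence = 0.95) {
  vals <- c(a_effect_mm2, a_fov_mm2, n_fov, flow_ccm, duration_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all sampling parameters must be strictly positive")
  if (n_fov != round(n_fov) || n_fov < 1) stop("'n_fov' must be an integer >= 1")
  if (n_fov * a_fov_mm2 > a_effect_mm2)
    stop("analyzed area n_fov * a_fov exceeds the effective filter area")
  if (confidence <= 0 || confidence >= 1) stop("'confidence' must be in (0, 1)")
  structure(list(a_effect_mm2 = a_effect_mm2, a_fov_mm2 = a_fov_mm2,
                 n_fov = as.integer(round(n_fov)), flow_ccm = flow_ccm,
                 duration_min = duration_min, confidence = confidence),
            class = "sampling_params")
}

#' Read sampling parameters from a YAML or JSON file
#' @param path File with the [sampling_params()] fields.
#' @return A `"sampling_params"` object.
#' @export
read_sampling_params <- function(path) {
  do.call(sampling_params, read_config_file(path))
}

#' Analytical sensitivity in f/cc per counted fiber
#'
#' `A_effect / (n * A_FOV * v * t)`: the airborne concentration that one
#' counted fiber represents, given that only `n` fields of `A_FOV` mm^2 of
#' an `A_effect` mm^2 filter were examined after sampling `v * t` cm^3 of
#' air. Homogeneous of degree +1 in the filter area and -1 in each of the
#' other four parameters.
#'
#' @param p A [sampling_params()] object.
#' @return Analytical sensitivity, f/cc per fiber.
#' @export
analytical_sensitivity <- function(p) {
  stopifnot(inherits(p, "sampling_params"))
  p$a_effect_mm2 / (p$n_fov * p$a_fov_mm2 * p$flow_ccm * p$duration_min)
}

# Exact (Garwood) Poisson count limits via chi-square quantiles.
# two-sided: lower = chisq(alpha/2, 2N)/2 (0 at N = 0),
#            upper = chisq(1 - alpha/2, 2N + 2)/2.
# One-sided upper at N = 0 and conf 0.95 is -log(0.05) = 2.996, the
# zero-count factor behind the limit of detection.
poisson_count_limits <- function(n, confidence = 0.95,
                                 sides = c("two", "upper")) {
  if (any(n < 0) || any(n != round(n))) stop("counts must be non-negative integers")
  sides <- match.arg(sides)
  alpha <- 1 - confidence
  if (sides == "two") {
    lower <- ifelse(n == 0, 0, 0.5 * stats::qchisq(alpha / 2, 2 * n))
    upper <- 0.5 * stats::qchisq(1 - alpha / 2, 2 * n + 2)
  } else {
    lower <- rep(0, length(n))
    upper <- 0.5 * stats::qchisq(confidence, 2 * n + 2)
  }
  cbind(lower = lower, upper = upper)
}

#' Convert a fiber count to an airborne concentration with Poisson bounds
#'
#' Concentration is `N` times the analytical sensitivity. The confidence
#' interval multiplies exact two-sided (Garwood) Poisson limits on the
#' count by the analytical sensitivity; the limit of detection is the
#' one-sided 95% upper bound at zero counts through the same code path.
#'
#' @param n Non-negative integer fiber count over the analyzed FOVs.
#' @param p A [sampling_params()] object.
#' @param confidence Two-sided confidence level (default from `p`).
#' @return An object of class `"concentration_estimate"`: list with
#'   `n_fibers`, `analytical_sensitivity`, `concentration_fcc`, `ci_fcc`
#'   (length 2), `lod_fcc`, `confidence`.
#' @export
count_to_concentration <- function(n, p, confidence = p$confidence) {
  stopifnot(inherits(p, "sampling_params"))
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != round(n))
    stop("'n' must be a single non-negative integer count")
  as_fcc <- analytical_sensitivity(p)
  lim <- poisson_count_limits(n, confidence, sides = "two")
  structure(list(n_fibers = as.integer(n),
                 analytical_sensitivity = as_fcc,
                 concentration_fcc = n * as_fcc,
                 ci_fcc = unname(c(lim[1, "lower"], lim[1, "upper"])) * as_fcc,
                 lod_fcc = limit_of_detection(p),
                 confidence = confidence),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("Fiber concentration: %.3g f/cc (N = %d, AS = %.4g f/cc per fiber)\n",
              x$concentration_fcc, x$n_fibers, x$analytical_sensitivity))
  cat(sprintf("  %.0f%% CI [%.3g, %.3g] f/cc; LOD %.3g f/cc\n",
              100 * x$confidence, x$ci_fcc[1], x$ci_fcc[2], x$lod_fcc))
  invisible(x)
}

#' Limit of detection in f/cc
#'
#' The concentration below which the true value lies with 95% confidence
#' when zero fibers are observed: the one-sided 95% Poisson upper count
#' bound at zero (`-ln(0.05) = 2.996` fibers) times the analytical
#' sensitivity. Doubling the sampled air volume or the analyzed area halves
#' it.
#'
#' @param p A [sampling_params()] object.
#' @param confidence One-sided confidence level (default 0.95).
#' @return Limit of detection, f/cc.
#' @export
limit_of_detection <- function(p, confidence = 0.95) {
  lim <- poisson_count_limits(0L, confidence, sides = "upper")
  unname(lim[1, "upper"]) * analytical_sensitivity(p)
}

#' Stopping rule for sequential FOV analysis
#'
#' Cap-based idiom of SEM filter-counting methods: stop once enough fibers
#' have been counted for the Poisson error to be acceptable, or once the
#' planned number of fields has been examined.
#'
#' @param fovs_analyzed Number of fields examined so far.
#' @param fibers_counted Running fiber count.
#' @param fiber_cap Stop at/above this many fibers (default 100).
#' @param n_max Stop at/above this many fields (default 25, the spiked-
#'   sample plan; 100 is typical for real-world filters).
#' @return List with `stop` (logical) and `reason` (`"fiber_cap"`,
#'   `"n_max"`, or `"continue"`).
#' @export
termination_check <- function(fovs_analyzed, fibers_counted,
                              fiber_cap = 100, n_max = 25) {
  if (fovs_analyzed < 0 || fibers_counted < 0)
    stop("running totals must be non-negative")
  if (fibers_counted >= fiber_cap)
    list(stop = TRUE, reason = "fiber_cap")
  else if (fovs_analyzed >= n_max)
    list(stop = TRUE, reason = "n_max")
  else
    list(stop = FALSE, reason = "continue")
}

#' Field-of-view centers along a radial transect
#'
#' Fields are placed edge to edge along a radius starting at the filter
#' center, the scan pattern that averages over uneven particle deposition.
#'
#' @param filter_radius_mm Radius of the effective filter area, mm.
#' @param a_fov_mm2 Area of one field of view, mm^2.
#' @param n_fov Number of fields.
#' @param aspect Width:height ratio of the field (default 4/3, e.g. a
#'   64 x 48 um field); the step along the transect is the field width
#'   `sqrt(a_fov * aspect)`.
#' @return Numeric vector of center distances from the filter center, mm.
#' @export
fov_transect <- function(filter_radius_mm, a_fov_mm2, n_fov, aspect = 4 / 3) {
  stopifnot(filter_radius_mm > 0, a_fov_mm2 > 0, n_fov >= 1)
  width <- sqrt(a_fov_mm2 * aspect)
  centers <- (seq_len(n_fov) - 1) * width
  if (centers[n_fov] + width / 2 > filter_radius_mm)
    stop(sprintf("transect of %d FOVs (%.3f mm) exceeds filter radius %.3f mm",
                 n_fov, centers[n_fov] + width / 2, filter_radius_mm))
  centers
}

#' Linear calibration of concentration against spiked mass fraction
#'
#' Ordinary least-squares fit of measured fiber concentration (f/cc) on the
#' erionite mass percentage of the bulk standards, with R^2 and a two-sided
#' t-test on the slope (n - 2 degrees of freedom).
#'
#' @param mass_pct Erionite mass percentages of the standards.
#' @param conc_fcc Measured concentrations, f/cc, paired with `mass_pct`.
#' @return An object of class `"calibration_fit"`: `slope` (f/cc per
#'   mass%), `intercept`, `r_squared`, `p_value`, `slope_ci` (95%),
#'   `n_points`, and the underlying `lm` fit as `model`.
#' @export
calibrate_standards <- function(mass_pct, conc_fcc) {
  ok <- stats::complete.cases(mass_pct, conc_fcc)
  x <- as.numeric(mass_pct[ok]); y <- as.numeric(conc_fcc[ok])
  if (length(x) < 3L) stop("calibration needs at least 3 paired points")
  if (stats::sd(x) == 0) stop("zero variance in mass percentages")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; zero-noise calibration data are valid here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  df <- length(x) - 2L
  r2 <- sm$r.squared
  if (stats::sd(y) == 0) { # flat response: no explainable variance
    slope <- 0; r2 <- 0
  }
  pval <- if (se == 0) (if (slope == 0) 1 else 0)
    else 2 * stats::pt(-abs(slope / se), df)
  tcrit <- stats::qt(0.975, df)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2, p_value = pval,
                 slope_ci = slope + c(-1, 1) * tcrit * se,
                 n_points = length(x), model = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  stars <- if (x$p_value < 0.001) "***"
    else if (x$p_value < 0.01) "**"
    else if (x$p_value < 0.05) "*" else ""
  cat(sprintf("Calibration: conc = %.4g + %.4g * mass%% (n = %d)\n",
              x$intercept, x$slope, x$n_points))
  cat(sprintf("  R^2 = %.3f, slope p = %.3g%s, slope 95%% CI [%.4g, %.4g]\n",
              x$r_squared, x$p_value, stars, x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}
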