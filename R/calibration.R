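# Calibration-curve fitting (Michaelis-Menten and linear), linear-range
# determination, and IUPAC detection limits in rate and concentration units.

#' Negative-control rate statistics
#'
#' Mean (`mu_c`) and standard deviation (`delta_c`) of the initial reaction
#' rate of negative controls, in uV/s. These feed the IUPAC detection limits.
#'
#' @param mu_c Mean control rate (uV/s).
#' @param delta_c SD of the control rate (uV/s); non-negative.
#' @param n Number of control measurements.
#' @return An object of class `negative_control_stats`.
#' @export
negative_control_stats <- function(mu_c, delta_c, n = NA_integer_) {
  stopifnot(is.finite(mu_c), is.finite(delta_c), delta_c >= 0)
  structure(list(mu_c = mu_c, delta_c = delta_c, n = n),
            class = "negative_control_stats")
}

#' Summarize extracted negative-control rates
#'
#' @param rates Vector of control initial rates (uV/s).
#' @return A [negative_control_stats()] object.
#' @export
summarize_negative_controls <- function(rates) {
  stopifnot(length(rates) >= 2)
  negative_control_stats(mean(rates), stats::sd(rates), length(rates))
}

r_squared <- function(y, fitted) {
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

#' Fit a Michaelis-Menten calibration curve
#'
#' Nonlinear least squares of `y = v_max * x / (k_m + x) + c` on
#' (concentration, rate) points, with bounded parameters
#' (`v_max` in (0, 100], `k_m` in (0, 1e6] uM, `c` free), initialization
#' `v_max = max(y)`, `k_m = median(x)`, and perturbed multi-starts on
#' non-convergence. Degenerate flat data (no spread in `y`) are handled by
#' returning a near-zero `v_max` with `c` at the mean rate.
#'
#' @param points A data.frame with columns `concentration_uM` and
#'   `rate_mV_per_s` (a two-column numeric matrix/data.frame is also
#'   accepted).
#' @param multistart Number of fitting starts.
#' @return A list with `params` ([mm_params()]) and `diagnostics` (list:
#'   `r2`, `rmse`, `param_sds`).
#' @export
fit_mm <- function(points, multistart = 4) {
  pts <- normalize_cal_points(points)
  x <- pts$x; y <- pts$y
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct concentrations for a Michaelis-Menten fit")
  if (stats::sd(y) < 1e-12 * (1 + abs(mean(y)))) {
    eps <- 1e-9
    params <- mm_params(v_max = eps, k_m = stats::median(x[x > 0]),
                        c = mean(y) - eps / 2)
    return(list(params = params,
                diagnostics = list(r2 = r_squared(y, mm_rate(x, params)),
                                   rmse = sqrt(mean((y - mm_rate(x, params))^2)),
                                   param_sds = c(v_max = NA, k_m = NA, c = NA))))
  }
  dat <- data.frame(x = x, y = y)
  v0 <- max(y) - min(0, min(y))
  k0 <- stats::median(x[x > 0])
  starts <- list(list(v_max = v0, k_m = k0, c = 0))
  for (i in seq_len(max(multistart - 1, 0))) {
    f <- 2^i
    starts[[length(starts) + 1L]] <- list(v_max = v0 * f, k_m = k0 * f, c = 0)
    starts[[length(starts) + 1L]] <- list(v_max = v0 / f, k_m = k0 / f, c = 0)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::nls(y ~ v_max * x / (k_m + x) + c, data = dat, start = s,
                 algorithm = "port",
                 lower = c(v_max = 1e-9, k_m = 1e-9, c = -Inf),
                 upper = c(v_max = 100, k_m = 1e6, c = Inf),
                 control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Michaelis-Menten fit did not converge")
  cf <- stats::coef(best$fit)
  params <- mm_params(cf[["v_max"]], cf[["k_m"]], cf[["c"]])
  sds <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                  error = function(e) c(v_max = NA, k_m = NA, c = NA))
  fitted <- mm_rate(x, params)
  list(params = params,
       diagnostics = list(r2 = r_squared(y, fitted),
                          rmse = sqrt(mean((y - fitted)^2)),
                          param_sds = sds))
}

normalize_cal_points <- function(points) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (all(c("concentration_uM", "rate_mV_per_s") %in% names(points))) {
    x <- points$concentration_uM; y <- points$rate_mV_per_s
  } else if (ncol(points) >= 2) {
    x <- points[[1]]; y <- points[[2]]
  } else stop("calibration points need concentration and rate columns")
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok])
}

#' Fit a linear calibration model
#'
#' Ordinary least squares `Y = S * x + C` on (concentration, rate) points,
#' with the slope reported per mM (input concentrations are uM).
#'
#' @param points As in [fit_mm()].
#' @param linear_range Optional length-2 interval (uM); points outside are
#'   dropped before fitting, and the interval is recorded in the result.
#' @return A [linear_cal()] object.
#' @export
fit_linear <- function(points, linear_range = NULL) {
  pts <- normalize_cal_points(points)
  x <- pts$x; y <- pts$y
  if (!is.null(linear_range)) {
    keep <- x >= linear_range[1] & x <= linear_range[2]
    x <- x[keep]; y <- y[keep]
  }
  if (length(unique(x)) < 2) stop("need at least 2 distinct concentrations")
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[[2]]
  if (slope <= 0) stop("non-positive calibration slope")
  rng <- if (is.null(linear_range)) range(x) else as.numeric(linear_range)
  linear_cal(s = slope * 1000, baseline = stats::coef(fit)[[1]],
             linear_range = rng,
             r2 = r_squared(y, stats::fitted(fit)),
             rmse = sqrt(mean(stats::residuals(fit)^2)))
}

#' Determine the linear range of a calibration series
#'
#' Finds the longest prefix `[0, x_k]` of the concentration-sorted points
#' (anchored at the lowest concentration) on which a straight-line fit keeps
#' `R^2` above the threshold. This matches the operational definition
#' "measurement range where the linear model had R^2 > 0.9".
#'
#' @param points As in [fit_mm()].
#' @param r2_threshold R-squared threshold.
#' @return Length-2 numeric interval (uM).
#' @export
linear_range <- function(points, r2_threshold = 0.9) {
  pts <- normalize_cal_points(points)
  ord <- order(pts$x)
  x <- pts$x[ord]; y <- pts$y[ord]
  ux <- unique(x)
  if (length(ux) < 3) stop("need at least 3 distinct concentrations")
  best_k <- NA
  for (k in 3:length(ux)) {
    keep <- x <= ux[k]
    fit <- stats::lm(y[keep] ~ x[keep])
    if (r_squared(y[keep], stats::fitted(fit)) > r2_threshold) best_k <- k
    else break
  }
  if (is.na(best_k))
    stop("no prefix of >= 3 concentrations is linear at the given threshold")
  c(min(x), ux[best_k])
}

#' IUPAC detection and quantification limits
#'
#' Computes the rate-domain limits `LOD = mu_c + 3.3 * delta_c` and
#' `LOQ = mu_c + 10 * delta_c` from negative-control statistics (uV/s),
#' reports them in mV/s, and converts them to concentration units by
#' inverting the Michaelis-Menten calibration with the offset excluded
#' ([mm_inverse()] with `include_offset = FALSE`). Rate-domain limits are
#' rounded to `rate_digits` decimals in mV/s (the platform's reporting
#' precision of 1 uV/s) before conversion, so concentration limits correspond
#' to the reported rate limits.
#'
#' @param nc A [negative_control_stats()] (uV/s).
#' @param p An [mm_params()] calibration.
#' @param rate_digits Decimals (in mV/s) at which rate limits are reported
#'   and converted; `NA` disables rounding.
#' @return An object of class `detection_limits`: list with `lod_rate`,
#'   `loq_rate` (mV/s) and `lod_conc`, `loq_conc` (uM).
#' @export
detection_limits <- function(nc, p, rate_digits = 3) {
  stopifnot(inherits(nc, "negative_control_stats"), inherits(p, "mm_params"))
  lod_rate <- (nc$mu_c + 3.3 * nc$delta_c) / 1000
  loq_rate <- (nc$mu_c + 10 * nc$delta_c) / 1000
  if (!is.na(rate_digits)) {
    lod_rate <- round(lod_rate, rate_digits)
    loq_rate <- round(loq_rate, rate_digits)
  }
  if (loq_rate >= p$v_max)
    stop("quantification limit at or above v_max: assay cannot quantify")
  structure(list(lod_rate = lod_rate, loq_rate = loq_rate,
                 lod_conc = mm_inverse(lod_rate, p),
                 loq_conc = mm_inverse(loq_rate, p)),
            class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("LOD: %.3f mV/s = %.1f uM; LOQ: %.3f mV/s = %.1f uM\n",
              x$lod_rate, x$lod_conc, x$loq_rate, x$loq_conc))
  invisible(x)
}
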