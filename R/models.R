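#' Michaelis-Menten calibration parameters
#'
#' Container for the saturating rate law `y = v_max * x / (k_m + x) + c`
#' linking substrate concentration `x` (uM) to initial reaction rate `y`
#' (mV/s). The offset `c` absorbs nonspecific background in the calibration
#' fit and may be negative.
#'
#' @param v_max Maximum rate (mV/s); must be positive.
#' @param k_m Half-saturation concentration (uM); must be positive.
#' @param c Rate offset (mV/s); finite, may be negative.
#' @return An object of class `mm_params`.
#' @examples
#' p <- mm_params(v_max = 3.63, k_m = 2866, c = -0.032)
#' mm_rate(1500, p)
#' @export
mm_params <- function(v_max, k_m, c = 0) {
  stopifnot(is.numeric(v_max), length(v_max) == 1L, is.finite(v_max), v_max > 0,
            is.numeric(k_m), length(k_m) == 1L, is.finite(k_m), k_m > 0,
            is.numeric(c), length(c) == 1L, is.finite(c))
  structure(list(v_max = v_max, k_m = k_m, c = c), class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("Michaelis-Menten: v_max = %.4g mV/s, k_m = %.4g uM, c = %.4g mV/s\n",
              x$v_max, x$k_m, x$c))
  invisible(x)
}

#' Michaelis-Menten rate
#'
#' Evaluates the initial reaction rate at substrate concentration `x`.
#'
#' @param x Substrate concentration (uM), non-negative; vectorized.
#' @param p An [mm_params()] object.
#' @return Rate(s) in mV/s.
#' @export
mm_rate <- function(x, p) {
  stopifnot(inherits(p, "mm_params"), is.numeric(x), all(is.finite(x)))
  if (any(x < 0)) stop("substrate concentration must be non-negative")
  p$v_max * x / (p$k_m + x) + p$c
}

#' Invert a Michaelis-Menten calibration
#'
#' Maps a rate back to a substrate concentration,
#' `x = k_m * y' / (v_max - y')`. By default the offset `c` is excluded
#' (`y' = y`); with `include_offset = TRUE` the offset is subtracted first
#' (`y' = y - c`), which makes the function the exact inverse of [mm_rate()].
#' The offset-excluded convention is the one used to translate rate-domain
#' detection limits into concentration units (see [detection_limits()]).
#'
#' @param y Rate (mV/s); vectorized.
#' @param p An [mm_params()] object.
#' @param include_offset Subtract `p$c` from `y` before inverting?
#' @return Concentration(s) in uM.
#' @export
mm_inverse <- function(y, p, include_offset = FALSE) {
  stopifnot(inherits(p, "mm_params"), is.numeric(y), all(is.finite(y)))
  yp <- if (include_offset) y - p$c else y
  if (any(yp < 0)) stop("rate below the invertible domain (y' < 0)")
  if (any(yp >= p$v_max))
    stop("rate at or above the v_max asymptote; concentration out of range")
  p$k_m * yp / (p$v_max - yp)
}

#' Linear calibration model
#'
#' Container for the straight-line calibration `Y = S * x + C` used inside
#' the linear range, with slope `s` reported per mM.
#'
#' @param s Sensitivity (mV/s per mM); must be positive.
#' @param baseline Rate intercept `C` (mV/s).
#' @param linear_range Length-2 concentration interval (uM), lower bound >= 0.
#' @param r2 Coefficient of determination of the fit.
#' @param rmse Root-mean-square residual (mV/s).
#' @return An object of class `linear_cal`.
#' @export
linear_cal <- function(s, baseline, linear_range = c(0, Inf), r2 = NA_real_,
                       rmse = NA_real_) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0,
            is.numeric(baseline), length(baseline) == 1L, is.finite(baseline),
            length(linear_range) == 2L, linear_range[1] >= 0,
            linear_range[1] < linear_range[2])
  structure(list(s = s, baseline = baseline,
                 linear_range = as.numeric(linear_range),
                 r2 = r2, rmse = rmse),
            class = "linear_cal")
}

#' @export
print.linear_cal <- function(x, ...) {
  cat(sprintf(
    "Linear calibration: S = %.4g mV/s/mM, baseline = %.4g mV/s, range [%g, %g] uM, R2 = %.4g\n",
    x$s, x$baseline, x$linear_range[1], x$linear_range[2], x$r2))
  invisible(x)
}

#' Photometric model of the illuminated photodiode
#'
#' Links chromophore concentration in the microfluidic channel to the sensor
#' voltage through the Beer-Lambert law:
#' `V(conc) = i_dark + (i_illum - i_dark) * 10^(-kappa * conc)`.
#' `kappa` is the effective molar absorptivity times optical path length per
#' uM of chromophore; `i_dark` and `i_illum` are the dark and illuminated
#' steady-state voltages of the photodiode.
#'
#' @param kappa Effective absorptivity x path length (per uM); >= 0.
#' @param i_dark Dark steady-state voltage (V).
#' @param i_illum Illuminated steady-state voltage (V); must exceed `i_dark`.
#' @return An object of class `photometric_model`.
#' @export
photometric_model <- function(kappa = 1e-4, i_dark = 0.486, i_illum = 1.730) {
  stopifnot(kappa >= 0, i_illum > i_dark)
  structure(list(kappa = kappa, i_dark = i_dark, i_illum = i_illum),
            class = "photometric_model")
}

#' Beer-Lambert voltage response
#'
#' @param chromophore_conc Chromophore concentration (uM), non-negative;
#'   vectorized.
#' @param pm A [photometric_model()].
#' @return Photodiode voltage (V); equals `i_illum` at zero concentration and
#'   decays monotonically toward `i_dark`.
#' @export
beer_lambert_voltage <- function(chromophore_conc, pm) {
  stopifnot(inherits(pm, "photometric_model"))
  if (any(chromophore_conc < 0)) stop("chromophore concentration must be >= 0")
  pm$i_dark + (pm$i_illum - pm$i_dark) * 10^(-pm$kappa * chromophore_conc)
}

#' Double-exponential reaction-progress model
#'
#' Empirical progress curve `y(t) = y0 + a1*(1 - exp(-k1 t)) + a2*(1 - exp(-k2 t))`
#' used to fit the binned channel signal. It reduces to the integrated
#' first-order limit of Michaelis-Menten kinetics when one amplitude is zero
#' and accommodates the slower second reaction stage through the second term.
#' The initial reaction rate is the analytic derivative at `t = 0`,
#' `a1*k1 + a2*k2`.
#'
#' @param y0 Signal intercept (mV).
#' @param a1,a2 Amplitudes (mV); sign carries the direction of signal change.
#' @param k1,k2 Rate constants (1/s); non-negative.
#' @return An object of class `double_exp_params`.
#' @export
double_exp_params <- function(y0, a1, k1, a2 = 0, k2 = 0) {
  stopifnot(is.finite(y0), is.finite(a1), is.finite(a2),
            is.finite(k1), is.finite(k2), k1 >= 0, k2 >= 0)
  structure(list(y0 = y0, a1 = a1, k1 = k1, a2 = a2, k2 = k2),
            class = "double_exp_params")
}

#' Evaluate the double-exponential progress model
#'
#' @param p A [double_exp_params()] object.
#' @param t Time(s) in seconds, non-negative; vectorized.
#' @return Signal value(s) (mV).
#' @export
double_exp_eval <- function(p, t) {
  stopifnot(inherits(p, "double_exp_params"))
  if (any(t < 0)) stop("t must be non-negative")
  p$y0 + p$a1 * (1 - exp(-p$k1 * t)) + p$a2 * (1 - exp(-p$k2 * t))
}

#' Initial slope of the double-exponential model
#'
#' Analytic derivative of [double_exp_eval()] at `t = 0`; this is the initial
#' reaction rate read off a fitted progress curve.
#'
#' @param p A [double_exp_params()] object.
#' @return Rate (mV/s).
#' @export
initial_slope <- function(p) {
  stopifnot(inherits(p, "double_exp_params"))
  p$a1 * p$k1 + p$a2 * p$k2
}
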