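# Standard-addition quantification: estimate an unknown sample's metabolite
# concentration from its test, negative-control, and two spiked
# (positive-control) initial reaction rates.

#' Background-correct a test rate
#'
#' Subtracts the sample-specific negative-control rate from the test rate,
#' `r_t* = r_t - r_n`. The result may be negative (below background).
#'
#' @param r_t Test rate.
#' @param r_n Negative-control rate (same units).
#' @return Adjusted rate `r_t*`.
#' @export
background_correct <- function(r_t, r_n) {
  stopifnot(is.finite(r_t), is.finite(r_n))
  r_t - r_n
}

#' Sample-specific sensitivities from standard addition
#'
#' Computes three secant estimates of the in-matrix sensitivity from the test
#' rate and the two spiked rates: `s1 = (r_b - r_a) / ([B] - [A])`,
#' `s2 = (r_b - r_t) / [B]`, `s3 = (r_a - r_t) / [A]`, and their average.
#' Because the spikes are added on top of the same sample, the concentration
#' differences in the denominators are exactly `[B] - [A]`, `[B]`, and `[A]`;
#' the common background cancels in every numerator, so no negative-control
#' correction of `r_a`/`r_b` is needed. A non-positive sensitivity flags a
#' failed standard addition.
#'
#' @param r_t,r_a,r_b Test and spiked rates (mV/s).
#' @param conc_a,conc_b Spike levels [A] < [B] (uM), both positive.
#' @return List with `s1`, `s2`, `s3`, `s_avg` (mV/s per uM) and `flag`
#'   (`NA` or `"nonpositive_sensitivity"`).
#' @export
sensitivities <- function(r_t, r_a, r_b, conc_a, conc_b) {
  stopifnot(conc_a > 0, conc_b > conc_a,
            is.finite(r_t), is.finite(r_a), is.finite(r_b))
  s1 <- (r_b - r_a) / (conc_b - conc_a)
  s2 <- (r_b - r_t) / conc_b
  s3 <- (r_a - r_t) / conc_a
  s_avg <- mean(c(s1, s2, s3))
  flag <- if (any(c(s1, s2, s3) <= 0)) "nonpositive_sensitivity" else NA_character_
  list(s1 = s1, s2 = s2, s3 = s3, s_avg = s_avg, flag = flag)
}

#' Quantify one sample by standard addition
#'
#' Completes the standard-addition computation for one sample and assay:
#' background correction `r_t* = r_t - r_n`, the three sensitivity variants
#' and their average `S`, and the concentration estimate `[T] = r_t* / S`.
#' A negative raw estimate (test below background) is reported as 0 with a
#' `below_background` flag; the raw value is retained for audit.
#'
#' @param r_t,r_n,r_a,r_b Test, negative-control, and spiked rates (mV/s).
#' @param conc_a,conc_b Spike levels [A] < [B] (uM).
#' @return An object of class `standard_addition`: all inputs, `r_t_star`,
#'   `s1`, `s2`, `s3`, `s_avg`, `t_est` (clipped at 0), `t_est_raw`, and
#'   `flag`.
#' @export
quantify <- function(r_t, r_n, r_a, r_b, conc_a, conc_b) {
  r_t_star <- background_correct(r_t, r_n)
  s <- sensitivities(r_t, r_a, r_b, conc_a, conc_b)
  flag <- s$flag
  if (!is.na(flag) || s$s_avg <= 0) {
    t_raw <- NA_real_
    flag <- if (is.na(flag)) "nonpositive_sensitivity" else flag
  } else {
    t_raw <- r_t_star / s$s_avg
    if (t_raw < 0) flag <- "below_background"
  }
  structure(list(r_t = r_t, r_n = r_n, r_a = r_a, r_b = r_b,
                 conc_a = conc_a, conc_b = conc_b,
                 r_t_star = r_t_star,
                 s1 = s$s1, s2 = s$s2, s3 = s$s3, s_avg = s$s_avg,
                 t_est_raw = t_raw,
                 t_est = if (is.na(t_raw)) NA_real_ else max(t_raw, 0),
                 flag = flag),
            class = "standard_addition")
}

#' @export
print.standard_addition <- function(x, ...) {
  cat(sprintf(
    "standard addition: r_t* = %.4g mV/s, S = %.4g mV/s/uM, [T] = %.4g uM%s\n",
    x$r_t_star, x$s_avg, x$t_est,
    if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Summarize replicate quantifications
#'
#' Arithmetic mean and sample SD of the concentration estimates over
#' unflagged replicates; flagged (anomalous) replicates are excluded.
#'
#' @param reps List of completed [quantify()] results, or a numeric vector of
#'   estimates.
#' @param flags Optional logical vector marking anomalous replicates (in
#'   addition to each replicate's own flag).
#' @return List with `mean`, `sd`, `n_used`.
#' @export
replicate_summary <- function(reps, flags = NULL) {
  if (is.numeric(reps)) {
    est <- reps
    bad <- rep(FALSE, length(est))
  } else {
    est <- vapply(reps, function(r) r$t_est, numeric(1))
    bad <- vapply(reps, function(r) !is.na(r$flag) &&
                    r$flag == "nonpositive_sensitivity", logical(1))
  }
  if (!is.null(flags)) bad <- bad | flags
  keep <- !bad & !is.na(est)
  if (!any(keep)) stop("no usable replicates")
  est <- est[keep]
  list(mean = mean(est),
       sd = if (length(est) > 1) stats::sd(est) else 0,
       n_used = length(est))
}

#' Quantify a simulated standard-addition cartridge run
#'
#' Convenience wrapper composing [extract_rate()] and [quantify()] on the
#' output of [simulate_sample_run()]: extracts the four channel rates, maps
#' them to their roles, and runs the standard-addition estimate.
#'
#' @param run Output of [simulate_sample_run()].
#' @param map Channel map used for the simulation.
#' @param config Signal-processing configuration (see [extract_rate()]).
#' @return A [quantify()] result with the extracted rates attached.
#' @export
quantify_sample_run <- function(run, map = default_channel_map(),
                                config = list()) {
  rates <- extract_rate(run$stack, map, config)
  r <- stats::setNames(rates$rate_mV_per_s, run$roles)
  quantify(r_t = r[["test"]], r_n = r[["negative"]],
           r_a = r[["posA"]], r_b = r[["posB"]],
           conc_a = run$spike_a, conc_b = run$spike_b)
}
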