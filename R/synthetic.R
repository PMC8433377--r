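# Seeded simulator replacing the physical cartridge: Michaelis-Menten product
# formation in four microfluidic channels, Beer-Lambert photometry on a 16x16
# photodiode array, sensor drift/noise/ADC quantization, clinical-style
# cohorts and calibration series.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Photodiode-array sensor model
#'
#' Acquisition parameters of the CMOS photodiode array: a 16 x 16 sensor
#' grid sampled at ~36.5 frames/s and digitized by a 12-bit ADC over a 3.3 V
#' full scale. `noise_sd` is white per-frame read noise; it also acts as
#' dither for the 0.8 mV ADC step. Drift defaults are the characterized
#' dark/illuminated baseline drifts. `dead_fraction` is the probability that
#' a sensor is unresponsive (frozen or railed).
#'
#' @param n_rows,n_cols Array dimensions.
#' @param frame_rate Frames per second.
#' @param adc_bits ADC resolution (bits).
#' @param adc_fullscale ADC full-scale voltage (V).
#' @param noise_sd Per-frame Gaussian read noise (V).
#' @param drift_dark,drift_illum Baseline drift (V/s) in the dark and under
#'   illumination.
#' @param dead_fraction Probability a sensor is unresponsive.
#' @param quantize Apply ADC quantization? Disable for an idealized sensor.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(n_rows = 16, n_cols = 16, frame_rate = 36.5,
                         adc_bits = 12, adc_fullscale = 3.3,
                         noise_sd = 1.5e-3,
                         drift_dark = 1.4e-6, drift_illum = 0.9e-6,
                         dead_fraction = 0.02, quantize = TRUE) {
  stopifnot(frame_rate > 0, adc_bits >= 1, dead_fraction >= 0,
            dead_fraction < 1, noise_sd >= 0, adc_fullscale > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols, frame_rate = frame_rate,
                 adc_bits = adc_bits, adc_fullscale = adc_fullscale,
                 noise_sd = noise_sd, drift_dark = drift_dark,
                 drift_illum = drift_illum, dead_fraction = dead_fraction,
                 quantize = quantize),
            class = "sensor_model")
}

#' Idealized sensor model
#'
#' The geometry and frame rate of [sensor_model()] with all instrument
#' imperfections switched off (no noise, no drift, no dead sensors, no ADC
#' quantization). Used to validate the signal-processing chain in isolation.
#'
#' @param ... Overrides passed to [sensor_model()].
#' @return A `sensor_model`.
#' @export
ideal_sensor_model <- function(...) {
  args <- utils::modifyList(
    list(noise_sd = 0, drift_dark = 0, drift_illum = 0,
         dead_fraction = 0, quantize = FALSE),
    list(...))
  do.call(sensor_model, args)
}

#' Effective kinetics of one assay channel
#'
#' Describes product (chromophore) formation in a channel as an effective
#' single-substrate Michaelis-Menten process: substrate is consumed at
#' `v_max_eff * S / (k_m_eff + S)` (uM/s) and chromophore accumulates with a
#' stoichiometric `chromophore_yield` (0.5 for the Trinder-type end reaction,
#' two H2O2 per dye molecule). `metabolite = "control"` marks a negative
#' control channel: no oxidase present, only a small nonspecific signal whose
#' rate is drawn from `control_rate_mean`/`control_rate_sd` (uV/s; defaults
#' 5.0 +/- 2.7 with liquid reagents, 23.0 +/- 12.5 in dried mode).
#'
#' @param metabolite Assay label, or `"control"`.
#' @param v_max_eff Maximum substrate-consumption rate (uM/s).
#' @param k_m_eff Effective Michaelis constant (uM).
#' @param chromophore_yield uM chromophore per uM substrate consumed.
#' @param reagent_mode `"liquid"` or `"dried"`.
#' @param control_rate_mean,control_rate_sd Negative-control rate statistics
#'   (uV/s); defaults follow `reagent_mode`.
#' @return An object of class `assay_kinetics`.
#' @export
assay_kinetics <- function(metabolite, v_max_eff = NA_real_, k_m_eff = NA_real_,
                           chromophore_yield = 0.5,
                           reagent_mode = c("liquid", "dried"),
                           control_rate_mean = NULL, control_rate_sd = NULL) {
  reagent_mode <- match.arg(reagent_mode)
  if (is.null(control_rate_mean))
    control_rate_mean <- if (reagent_mode == "liquid") 5.0 else 23.0
  if (is.null(control_rate_sd))
    control_rate_sd <- if (reagent_mode == "liquid") 2.7 else 12.5
  stopifnot(control_rate_sd >= 0, chromophore_yield > 0)
  if (!identical(metabolite, "control")) {
    stopifnot(is.finite(v_max_eff), v_max_eff > 0,
              is.finite(k_m_eff), k_m_eff > 0)
  }
  structure(list(metabolite = metabolite, v_max_eff = v_max_eff,
                 k_m_eff = k_m_eff, chromophore_yield = chromophore_yield,
                 reagent_mode = reagent_mode,
                 control_rate_mean = control_rate_mean,
                 control_rate_sd = control_rate_sd),
            class = "assay_kinetics")
}

# mV of initial voltage-signal change per uM of substrate consumed, for a
# given photometric model and stoichiometric yield (small-absorbance limit).
signal_gain_mV_per_uM <- function(pm, yield) {
  (pm$i_illum - pm$i_dark) * 1000 * log(10) * pm$kappa * yield
}

#' Assay kinetics matched to a panel calibration
#'
#' Builds an [assay_kinetics()] whose simulated voltage-domain initial rate
#' reproduces the panel calibration of [panel_assays()]. With
#' `model = "mm"` (default), the initial voltage rate at substrate
#' concentration `x` equals `v_max * x / (k_m + x)` (mV/s) with the tabulated
#' Michaelis-Menten parameters (offset `c` excluded; it is a calibration fit
#' artifact, not a physical rate). With `model = "linear"` the kinetics are
#' exactly first order with initial voltage rate `sens * x` (the tabulated
#' linear-model sensitivity), i.e. the platform operating strictly inside its
#' linear range; this mode isolates pipeline error from the saturation
#' curvature of the global calibration curve.
#'
#' @param metabolite Panel metabolite, or `"control"`.
#' @param pm A [photometric_model()].
#' @param mode Reagent mode.
#' @param chromophore_yield uM chromophore per uM substrate.
#' @param model `"mm"` (saturating calibration curve) or `"linear"`.
#' @param ... Further arguments (e.g. `control_rate_mean`, `control_rate_sd`)
#'   passed to [assay_kinetics()].
#' @return An `assay_kinetics`.
#' @export
panel_kinetics <- function(metabolite, pm = photometric_model(),
                           mode = "liquid", chromophore_yield = 0.5,
                           model = c("mm", "linear"), ...) {
  model <- match.arg(model)
  if (identical(metabolite, "control"))
    return(assay_kinetics("control", reagent_mode = mode,
                          chromophore_yield = chromophore_yield, ...))
  tab <- panel_assays(mode)
  row <- tab[tab$metabolite == metabolite, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown metabolite: ", metabolite)
  g <- signal_gain_mV_per_uM(pm, chromophore_yield)
  if (model == "mm") {
    assay_kinetics(metabolite,
                   v_max_eff = row$v_max / g,
                   k_m_eff = row$k_m,
                   chromophore_yield = chromophore_yield,
                   reagent_mode = mode, ...)
  } else {
    # exactly first order: k_m far above any concentration in use, with
    # v_max/k_m fixed at the linear sensitivity (converted to per uM)
    k_big <- 1e9
    assay_kinetics(metabolite,
                   v_max_eff = (row$sens / 1000) / g * k_big,
                   k_m_eff = k_big,
                   chromophore_yield = chromophore_yield,
                   reagent_mode = mode, ...)
  }
}

#' Default channel map of the four-channel cartridge
#'
#' Assigns the 16 x 16 sensors to the four parallel microfluidic channels:
#' each channel covers a 3-column band of 48 sensors, separated by 1-column
#' walls (sensors under walls belong to no channel).
#'
#' @param n_rows,n_cols Array dimensions.
#' @return An object of class `channel_map`: a list with `channel` (integer
#'   matrix, `NA` under walls) and `excluded` (logical matrix).
#' @export
default_channel_map <- function(n_rows = 16, n_cols = 16) {
  ch <- matrix(NA_integer_, n_rows, n_cols)
  for (k in 1:4) ch[, (4 * k - 2):(4 * k)] <- k
  structure(list(channel = ch,
                 excluded = matrix(FALSE, n_rows, n_cols)),
            class = "channel_map")
}

#' Simulate reaction progress in one channel
#'
#' Integrates the effective kinetics `dS/dt = -v(S)`,
#' `dP/dt = v(S) * chromophore_yield` with
#' `v(S) = v_max_eff * S / (k_m_eff + S)` by classical fixed-step RK4,
#' starting from `S(0) = substrate0`, `P(0) = 0`. Mass balance
#' `S + P / yield = substrate0` holds exactly because `P` is computed from the
#' integrated substrate.
#'
#' @param kin An [assay_kinetics()] (non-control).
#' @param substrate0 Initial substrate concentration (uM).
#' @param duration Total time (s).
#' @param dt Output time step (s); rejected if too coarse for the kinetics.
#' @return A data.frame with columns `time`, `substrate`, `product` (uM).
#' @export
simulate_progress <- function(kin, substrate0, duration, dt) {
  stopifnot(inherits(kin, "assay_kinetics"), substrate0 >= 0,
            duration > 0, dt > 0)
  if (identical(kin$metabolite, "control"))
    stop("control channels have no substrate kinetics")
  kmax <- kin$v_max_eff / kin$k_m_eff
  if (dt * kmax > 0.5)
    stop("dt too coarse for the kinetics (dt * v_max/k_m must be <= 0.5)")
  times <- seq(0, duration, by = dt)
  n <- length(times)
  v <- function(s) kin$v_max_eff * s / (kin$k_m_eff + s)
  s <- numeric(n)
  s[1] <- substrate0
  for (i in seq_len(n - 1L)) {
    si <- s[i]
    r1 <- -v(si)
    r2 <- -v(max(si + dt / 2 * r1, 0))
    r3 <- -v(max(si + dt / 2 * r2, 0))
    r4 <- -v(max(si + dt * r3, 0))
    s[i + 1L] <- max(si + dt / 6 * (r1 + 2 * r2 + 2 * r3 + r4), 0)
  }
  data.frame(time = times, substrate = s,
             product = (substrate0 - s) * kin$chromophore_yield)
}

# ADC quantization: clip to [0, fullscale] and round to LSB multiples.
adc_quantize <- function(v, sm) {
  if (!isTRUE(sm$quantize)) return(pmin(pmax(v, 0), sm$adc_fullscale))
  lsb <- sm$adc_fullscale / 2^sm$adc_bits
  pmin(pmax(round(v / lsb) * lsb, 0), sm$adc_fullscale)
}

#' Simulate a full photodiode frame stack for one cartridge run
#'
#' Produces the raw sensor record of one acquisition: per live sensor,
#' voltage = Beer-Lambert response to the channel's chromophore trace +
#' sample background + baseline drift * t + Gaussian read noise, then ADC
#' quantization. The nonspecific sample background is a linear signal whose
#' rate is drawn once per cartridge from the negative-control statistics and
#' is shared by all four channels (they see the same sample); negative
#' control channels (kinetics labeled `"control"`) show only this background,
#' which is what makes the downstream `r_t - r_n` correction cancel it. Dead
#' sensors (probability `sm$dead_fraction`) are frozen at their initial value
#' or railed at 0 / full scale. Sensors under walls see the dark baseline.
#'
#' @param conc Numeric vector: substrate concentration (uM) per channel
#'   (ignored for control channels).
#' @param kinetics List of [assay_kinetics()], one per channel.
#' @param map A [default_channel_map()]-style channel map.
#' @param sm A [sensor_model()].
#' @param pm A [photometric_model()].
#' @param duration Acquisition length (s); 300 s at 36.5 fps gives 10950
#'   frames.
#' @param seed Integer seed; the stack is a deterministic function of its
#'   arguments.
#' @return An object of class `frame_stack`: list with `times` (s),
#'   `frames` (matrix, frames x sensors, sensors in column-major (row, col)
#'   order), `n_rows`, `n_cols`, and `meta`.
#' @export
simulate_frame_stack <- function(conc, kinetics, map = default_channel_map(),
                                 sm = sensor_model(), pm = photometric_model(),
                                 duration = 300, seed = 1L) {
  n_ch <- max(map$channel, na.rm = TRUE)
  stopifnot(length(conc) == n_ch, length(kinetics) == n_ch)
  for (k in kinetics) stopifnot(inherits(k, "assay_kinetics"))
  nframes <- as.integer(round(duration * sm$frame_rate))
  times <- (seq_len(nframes) - 1L) / sm$frame_rate
  nsens <- sm$n_rows * sm$n_cols
  with_seed(seed, {
    # nonspecific sample background (uV/s), one draw per cartridge
    r_bg <- stats::rnorm(1, kinetics[[1]]$control_rate_mean,
                         kinetics[[1]]$control_rate_sd)
    bg <- -r_bg * 1e-6 * times
    # per-channel ideal signal (V)
    sig <- matrix(NA_real_, nframes, n_ch)
    for (ch in seq_len(n_ch)) {
      kin <- kinetics[[ch]]
      if (identical(kin$metabolite, "control") || conc[ch] <= 0) {
        sig[, ch] <- pm$i_illum + bg
      } else {
        prog <- simulate_progress(kin, conc[ch], duration, 1 / sm$frame_rate)
        p_t <- prog$product[seq_len(nframes)]
        sig[, ch] <- beer_lambert_voltage(p_t, pm) + bg
      }
    }
    frames <- matrix(pm$i_dark, nframes, nsens) +
      outer(times, rep(sm$drift_dark, nsens))
    ch_of <- as.integer(map$channel)          # column-major flattening
    for (ch in seq_len(n_ch)) {
      idx <- which(ch_of == ch)
      frames[, idx] <- sig[, ch] + sm$drift_illum * times
    }
    if (sm$noise_sd > 0)
      frames <- frames + matrix(stats::rnorm(nframes * nsens, 0, sm$noise_sd),
                                nframes, nsens)
    dead <- stats::runif(nsens) < sm$dead_fraction
    for (j in which(dead)) {
      mode_j <- sample(c("frozen", "rail0", "rail1"), 1L)
      frames[, j] <- switch(mode_j,
                            frozen = frames[1L, j],
                            rail0 = 0,
                            rail1 = sm$adc_fullscale)
    }
    frames <- adc_quantize(frames, sm)
    structure(list(times = times, frames = frames,
                   n_rows = sm$n_rows, n_cols = sm$n_cols,
                   meta = list(illuminated = TRUE,
                               temperature_C = 26.5, humidity_pct = 48,
                               seed = seed, frame_rate = sm$frame_rate,
                               adc_bits = sm$adc_bits,
                               adc_fullscale = sm$adc_fullscale,
                               quantized = isTRUE(sm$quantize),
                               duration_s = duration,
                               channels = vapply(kinetics, `[[`, "",
                                                 "metabolite"),
                               conc_uM = conc,
                               background_rate_uVs = r_bg)),
              class = "frame_stack")
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frames x %d sensors (%dx%d), %.1f fps, %.0f s\n",
              nrow(x$frames), ncol(x$frames), x$n_rows, x$n_cols,
              x$meta$frame_rate, x$meta$duration_s))
  invisible(x)
}

#' Group specification for cohort simulation
#'
#' @param label Group label (e.g. `"non-PCa"`, `"PCa"`).
#' @param n Number of samples.
#' @param mean,sd Named numeric vectors of per-metabolite concentration mean
#'   and SD (uM); names define the metabolites.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, n, mean, sd) {
  stopifnot(n >= 1, all(sd >= 0), all(mean > 0),
            identical(names(mean), names(sd)), !is.null(names(mean)))
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_spec")
}

# truncated-normal (at 0) draw by rejection
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < 0)
  }
  out
}

#' Simulate a clinical-style cohort table
#'
#' Draws per-sample metabolite concentrations independently per metabolite
#' from normal distributions truncated at zero, with group-specific means and
#' SDs, and attaches the binary group label. Independence across metabolites
#' reflects the observed absence of relevant cross-correlation (< 0.3).
#'
#' @param groups List of [group_spec()]; defaults to the published clinical
#'   group statistics.
#' @param seed Integer seed.
#' @return A `cohort_table` data.frame: `sample_id`, `group`, one
#'   concentration column (uM) per metabolite.
#' @export
simulate_cohort <- function(groups = cohort_group_defaults(), seed = 1L) {
  mets <- names(groups[[1]]$mean)
  with_seed(seed, {
    rows <- lapply(groups, function(g) {
      stopifnot(identical(names(g$mean), mets))
      d <- as.data.frame(lapply(mets, function(m)
        rtruncnorm0(g$n, g$mean[[m]], g$sd[[m]])))
      names(d) <- mets
      cbind(data.frame(group = rep(g$label, g$n)), d)
    })
    out <- do.call(rbind, rows)
    out <- cbind(data.frame(sample_id = seq_len(nrow(out))), out)
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Simulate a calibration series
#'
#' Generates a (concentration, rate) calibration table by evaluating the
#' true Michaelis-Menten curve and applying multiplicative Gaussian noise
#' `rate = mm_rate(x) * (1 + eps)`, `eps ~ N(0, noise_rel)`, matching the
#' 16-20% relative replicate SD observed on the platform.
#'
#' @param metabolite Panel metabolite (sets default true parameters and
#'   noise level).
#' @param concentrations Concentration grid (uM); at least two distinct
#'   values.
#' @param replicates Replicates per concentration.
#' @param noise_rel Relative rate SD; defaults to the panel value.
#' @param seed Integer seed.
#' @param params Optional [mm_params()] overriding the panel truth.
#' @return A data.frame with columns `metabolite`, `concentration_uM`,
#'   `rate_mV_per_s`, `replicate`.
#' @export
make_calibration_series <- function(metabolite, concentrations,
                                    replicates = 3, noise_rel = NULL,
                                    seed = 1L, params = NULL) {
  if (length(concentrations) < 2)
    stop("need at least two concentration points")
  if (is.null(params)) params <- panel_mm_params(metabolite)
  if (is.null(noise_rel)) {
    tab <- panel_assays()
    noise_rel <- tab$noise_rel[tab$metabolite == metabolite]
    if (length(noise_rel) != 1L) noise_rel <- 0.18
  }
  x <- rep(concentrations, each = replicates)
  rep_id <- rep(seq_len(replicates), times = length(concentrations))
  truth <- mm_rate(x, params)
  with_seed(seed, {
    eps <- if (noise_rel > 0) stats::rnorm(length(x), 0, noise_rel) else 0
    data.frame(metabolite = metabolite, concentration_uM = x,
               rate_mV_per_s = truth * (1 + eps), replicate = rep_id)
  })
}

#' Simulate one standard-addition sample run as a four-channel cartridge
#'
#' Lays out the clinical per-sample protocol on one cartridge: channel 1 is
#' the negative control, channel 2 the test sample at the unknown
#' concentration, channels 3 and 4 the positive controls spiked with [A] and
#' [B] = 2[A] on top of the sample.
#'
#' @param metabolite Panel metabolite.
#' @param true_conc Endogenous concentration (uM).
#' @param seed Integer seed.
#' @param duration Acquisition length (s).
#' @param sm,pm Sensor and photometric models.
#' @param spike_a Spike level [A] (uM); defaults to the panel protocol
#'   (500 uM for LAA, 100 uM otherwise).
#' @param model Calibration model driving the kinetics; see
#'   [panel_kinetics()].
#' @return A list with the `frame_stack` (`stack`), channel `roles`
#'   (`negative`, `test`, `posA`, `posB`), spike levels, and the truth.
#' @export
simulate_sample_run <- function(metabolite, true_conc, seed = 1L,
                                duration = 300, sm = sensor_model(),
                                pm = photometric_model(), spike_a = NULL,
                                model = "mm") {
  tab <- panel_assays()
  row <- tab[tab$metabolite == metabolite, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown metabolite: ", metabolite)
  if (is.null(spike_a)) spike_a <- row$spike_a
  kin <- panel_kinetics(metabolite, pm, model = model)
  kin_ctrl <- panel_kinetics("control", pm)
  stack <- simulate_frame_stack(
    conc = c(0, true_conc, true_conc + spike_a, true_conc + 2 * spike_a),
    kinetics = list(kin_ctrl, kin, kin, kin),
    sm = sm, pm = pm, duration = duration, seed = seed)
  list(stack = stack,
       roles = c("negative", "test", "posA", "posB"),
       metabolite = metabolite, spike_a = spike_a, spike_b = 2 * spike_a,
       true_conc = true_conc)
}
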