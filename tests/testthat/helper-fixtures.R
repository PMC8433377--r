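# In-code fixtures shared across test files.

# Direct arithmetic oracle for the saturating calibration curve, independent
# of the package's mm_rate() implementation.
oracle_mm <- function(x, v_max, k_m, c = 0) v_max * x / (k_m + x) + c

# Build a frame_stack directly from per-channel signals (V), bypassing the
# simulator, for unit tests of the processing chain.
stack_from_signals <- function(times, signals, map = default_channel_map(),
                               n_rows = 16, n_cols = 16, fullscale = 3.3,
                               frame_rate = NULL) {
  signals <- as.matrix(signals)
  stopifnot(nrow(signals) == length(times))
  frames <- matrix(0, length(times), n_rows * n_cols)
  ch_of <- as.integer(map$channel)
  for (ch in seq_len(ncol(signals))) {
    frames[, which(ch_of == ch)] <- signals[, ch]
  }
  if (is.null(frame_rate)) frame_rate <- 1 / mean(diff(times))
  structure(list(times = times, frames = frames,
                 n_rows = n_rows, n_cols = n_cols,
                 meta = list(adc_fullscale = fullscale,
                             frame_rate = frame_rate,
                             duration_s = max(times),
                             quantized = FALSE)),
            class = "frame_stack")
}

# A single-channel map (channel 1 only, 48 sensors) to keep per-run
# processing cheap in Monte-Carlo tests.
one_channel_map <- function(n_rows = 16, n_cols = 16) {
  ch <- matrix(NA_integer_, n_rows, n_cols)
  ch[, 2:4] <- 1L
  structure(list(channel = ch, excluded = matrix(FALSE, n_rows, n_cols)),
            class = "channel_map")
}

# Noise-free kinetics helpers (no sample background) for oracle stacks.
quiet_kinetics <- function(metabolite, pm = photometric_model(), ...) {
  panel_kinetics(metabolite, pm, control_rate_mean = 0,
                 control_rate_sd = 0, ...)
}
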