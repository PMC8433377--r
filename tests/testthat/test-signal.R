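pm <- photometric_model()

test_that("bad-sensor screens catch railed, frozen and outlier sensors", {
  times <- seq(0, 30, by = 0.25)
  ramp <- 1.5 - 1e-3 * times
  st <- stack_from_signals(times, cbind(ramp, ramp, ramp, ramp))
  map <- default_channel_map()
  # all-identical healthy sensors: nothing flagged
  expect_true(!any(detect_bad_sensors(st, map)))
  # one sensor railed at 0 V among healthy peers: exactly that one flagged
  st0 <- st
  st0$frames[, 20] <- 0            # sensor 20 = (row 4, col 2), channel 1
  ex <- detect_bad_sensors(st0, map)
  expect_identical(which(as.vector(ex)), 20L)
  # one frozen sensor (constant while peers move + tiny noise)
  stf <- st
  set.seed(1)
  live <- which(!is.na(as.integer(map$channel)))
  stf$frames[, live] <- stf$frames[, live] + rnorm(length(times) *
                                                     length(live), 0, 1e-4)
  stf$frames[, 25] <- 1.5
  exf <- detect_bad_sensors(stf, map)
  expect_true(as.vector(exf)[25])
  # slope outlier against channel peers
  sts <- stf
  sts$frames[, 30] <- 1.5 - 8e-3 * times
  expect_true(as.vector(detect_bad_sensors(sts, map))[30])
})

test_that("simulated dead sensors are flagged at the configured fraction", {
  # 40 seeded short stacks (scaled down from 100; same 3-SE check)
  kin <- quiet_kinetics("choline", pm)
  map <- default_channel_map()
  n_flagged <- vapply(1:40, function(s) {
    st <- simulate_frame_stack(c(10, 0, 5, 20), rep(list(kin), 4),
                               sm = sensor_model(dead_fraction = 0.02),
                               pm = pm, duration = 15, seed = 2000 + s)
    sum(detect_bad_sensors(st, map))
  }, numeric(1))
  n_live <- 192
  frac <- mean(n_flagged) / n_live
  se <- sqrt(0.02 * 0.98 / (40 * n_live))
  expect_lt(abs(frac - 0.02), 3 * se + 1e-3)
})

test_that("channel averaging reduces iid noise like 1/sqrt(n)", {
  times <- seq(0, 50, by = 0.5)
  map <- default_channel_map()
  sds <- vapply(1:6, function(s) {
    set.seed(s)
    st <- stack_from_signals(times, matrix(1.2, length(times), 4))
    live <- which(!is.na(as.integer(map$channel)))
    st$frames[, live] <- st$frames[, live] +
      rnorm(length(times) * length(live), 0, 0.01)
    tr <- channel_trace(st, map)
    sd(tr[, 1])
  }, numeric(1))
  expect_equal(mean(sds), 0.01 / sqrt(48), tolerance = 0.1)
  # identical sensors: average equals any single sensor
  st <- stack_from_signals(times, cbind(1.1 + 0.001 * times, 1, 1, 1))
  tr <- channel_trace(st, map)
  expect_equal(tr[, 1], st$frames[, 18], tolerance = 1e-12)
  # an excluded outlier does not perturb the mean
  stx <- st
  stx$frames[, 20] <- 3
  ex <- matrix(FALSE, 16, 16); ex[4, 2] <- TRUE
  trx <- channel_trace(stx, map, ex)
  expect_equal(trx[, 1], tr[, 1], tolerance = 1e-12)
  expect_equal(attr(trx, "n_sensors")[1], 47)
})

test_that("temporal binning drops partial windows and preserves slopes", {
  # 300 s at 36.5 fps -> 300 one-second bins
  times <- (0:10949) / 36.5
  b <- temporal_bin(rep(1, length(times)), times, window = 1)
  expect_length(b$values, 300)
  expect_true(all(b$values == 1))
  # linear ramp: binned series has the same slope (integer frames per window)
  t2 <- (0:999) / 40
  ramp <- 0.3 + 2.5 * t2
  b2 <- temporal_bin(ramp, t2, window = 1)
  slope <- coef(lm(b2$values ~ b2$times))[[2]]
  expect_equal(slope, 2.5, tolerance = 1e-9)
  expect_error(temporal_bin(rep(1, 10), seq(0, 0.9, 0.1), window = 1),
               "two windows")
})

test_that("extract_rate recovers configured rates on noiseless stacks", {
  # exactly first-order kinetics, ideal sensor: within 1 %
  kin <- quiet_kinetics("choline", pm, model = "linear")
  truth <- function(conc) {
    tab <- panel_assays()
    tab$sens[tab$metabolite == "choline"] / 1000 * conc
  }
  st <- simulate_frame_stack(c(50, 0, 25, 100), rep(list(kin), 4),
                             sm = ideal_sensor_model(), pm = pm,
                             duration = 60, seed = 5)
  rr <- extract_rate(st)
  expect_equal(rr$rate_mV_per_s[1], truth(50), tolerance = 0.01)
  expect_equal(rr$rate_mV_per_s[3], truth(25), tolerance = 0.01)
  expect_equal(rr$rate_mV_per_s[4], truth(100), tolerance = 0.01)
  expect_true(all(!rr$anomalous))
  # saturating kinetics with the default (quantizing) sensor: within 2 %
  kmm <- quiet_kinetics("LAA", pm)
  st2 <- simulate_frame_stack(c(1500, 0, 750, 300), rep(list(kmm), 4),
                              sm = sensor_model(dead_fraction = 0),
                              pm = pm, duration = 120, seed = 6)
  rr2 <- extract_rate(st2)
  for (i in c(1, 3, 4)) {
    conc <- c(1500, 0, 750, 300)[i]
    expect_equal(rr2$rate_mV_per_s[i], oracle_mm(conc, 3.63, 2866),
                 tolerance = 0.02)
  }
})

test_that("a flat illuminated stack reports the baseline drift", {
  kin <- quiet_kinetics("LAA", pm)
  st <- simulate_frame_stack(c(0, 0, 0, 0), rep(list(kin), 4),
                             sm = ideal_sensor_model(drift_illum = 0.9e-6),
                             pm = pm, duration = 300, seed = 2)
  rr <- extract_rate(st)
  expect_equal(rr$rate_mV_per_s * 1000, rep(0.9, 4), tolerance = 0.05)
})

test_that("a zero stack yields zero rates", {
  times <- seq(0, 30, 0.25)
  st <- stack_from_signals(times, matrix(0, length(times), 4))
  rr <- extract_rate(st)
  expect_equal(rr$rate_mV_per_s, rep(0, 4))
})

test_that("the pipeline is offset-equivariant and amplitude-linear", {
  times <- seq(0, 120, 1 / 36.5)
  k <- 0.02
  sig <- function(amp) 1.6 - amp * (1 - exp(-k * times))
  base <- cbind(sig(0.05), sig(0.02), sig(0.08), sig(0.03))
  st <- stack_from_signals(times, base)
  r0 <- extract_rate(st)$rate_mV_per_s
  # voltage offset leaves rates unchanged
  st_off <- st
  st_off$frames <- st_off$frames + 0.25
  expect_equal(extract_rate(st_off)$rate_mV_per_s, r0, tolerance = 1e-6)
  # amplitude scale multiplies the rate
  lam <- 2.5
  st_sc <- stack_from_signals(times, 1.6 - lam * (1.6 - base))
  expect_equal(extract_rate(st_sc)$rate_mV_per_s, lam * r0,
               tolerance = 0.01)
  # sanity: the unscaled rates match the analytic initial slope amp*k (mV/s)
  expect_equal(r0, c(0.05, 0.02, 0.08, 0.03) * 1000 * k, tolerance = 0.005)
})
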