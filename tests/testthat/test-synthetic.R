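pm <- photometric_model()

test_that("simulate_progress integrates the effective kinetics", {
  kin <- panel_kinetics("LAA", pm)
  # zero substrate -> no product
  p0 <- simulate_progress(kin, 0, duration = 10, dt = 0.1)
  expect_true(all(p0$product == 0))
  # mass balance holds exactly at every step
  pr <- simulate_progress(kin, 1500, duration = 60, dt = 0.05)
  expect_equal(pr$substrate + pr$product / kin$chromophore_yield,
               rep(1500, nrow(pr)), tolerance = 1e-9)
  # far below k_m the progress is first order within 1 %
  s0 <- kin$k_m_eff / 100
  k <- kin$v_max_eff / kin$k_m_eff
  pr1 <- simulate_progress(kin, s0, duration = 120, dt = 0.05)
  closed <- s0 * kin$chromophore_yield * (1 - exp(-k * pr1$time))
  expect_equal(pr1$product[-1], closed[-1], tolerance = 0.01)
  # initial product rate matches the rate law within 0.5 %
  prf <- simulate_progress(kin, 1500, duration = 1, dt = 1e-3)
  dpdt <- (prf$product[2] - prf$product[1]) / 1e-3
  v0 <- kin$chromophore_yield * kin$v_max_eff * 1500 / (kin$k_m_eff + 1500)
  expect_equal(dpdt, v0, tolerance = 5e-3)
  expect_error(simulate_progress(kin, 100, duration = 10, dt = 1e4),
               "too coarse")
})

test_that("a 5-minute acquisition at 36.5 fps has 10950 frames", {
  kin <- quiet_kinetics("choline", pm)
  st <- simulate_frame_stack(c(0, 0, 0, 0), rep(list(kin), 4),
                             sm = sensor_model(noise_sd = 0,
                                               dead_fraction = 0),
                             pm = pm, duration = 300, seed = 1)
  expect_identical(nrow(st$frames), 10950L)
  expect_true(all(diff(st$times) > 0))
})

test_that("zero concentration, zero noise/drift gives the illuminated level", {
  kin <- quiet_kinetics("choline", pm)
  st <- simulate_frame_stack(c(0, 0, 0, 0), rep(list(kin), 4),
                             sm = ideal_sensor_model(), pm = pm,
                             duration = 5, seed = 1)
  map <- default_channel_map()
  live <- which(!is.na(as.integer(map$channel)))
  expect_true(all(st$frames[, live] == 1.730))
})

test_that("frame stacks are seeded deterministically and ADC-quantized", {
  kin <- panel_kinetics("glutamate", pm)
  sm <- sensor_model()
  a <- simulate_frame_stack(c(100, 0, 50, 200), rep(list(kin), 4),
                            sm = sm, pm = pm, duration = 6, seed = 7)
  b <- simulate_frame_stack(c(100, 0, 50, 200), rep(list(kin), 4),
                            sm = sm, pm = pm, duration = 6, seed = 7)
  expect_identical(a$frames, b$frames)
  d <- simulate_frame_stack(c(100, 0, 50, 200), rep(list(kin), 4),
                            sm = sm, pm = pm, duration = 6, seed = 8)
  expect_false(identical(a$frames, d$frames))
  lsb <- sm$adc_fullscale / 2^sm$adc_bits
  expect_equal(a$frames, round(a$frames / lsb) * lsb, tolerance = 1e-12)
})

test_that("cohort simulation reproduces the group specifications", {
  mets <- c("LAA", "glutamate")
  gs <- list(group_spec("ctl", 5, mean = c(LAA = 2000, glutamate = 40),
                        sd = c(LAA = 0, glutamate = 0)),
             group_spec("case", 7, mean = c(LAA = 2700, glutamate = 60),
                        sd = c(LAA = 0, glutamate = 0)))
  co <- simulate_cohort(gs, seed = 1)
  expect_equal(nrow(co), 12)
  expect_true(all(co$LAA[co$group == "ctl"] == 2000))
  expect_true(all(co$glutamate[co$group == "case"] == 60))
  # law of large numbers: sample mean within 1 % of the specified mean when
  # the zero-truncation is negligible (LAA-like: mean/sd ~ 3.8)
  big <- list(group_spec("g", 1e5, mean = c(LAA = 1984), sd = c(LAA = 527)))
  cb <- simulate_cohort(big, seed = 2)
  expect_equal(mean(cb$LAA), 1984, tolerance = 0.01)
  # heavy truncation (choline-like) matches the analytic truncated-normal
  # mean: mu + sd * dnorm(mu/sd) / pnorm(mu/sd)
  tr <- list(group_spec("g", 1e5, mean = c(choline = 13.4),
                        sd = c(choline = 7.9)))
  ct <- simulate_cohort(tr, seed = 2)
  mu_trunc <- 13.4 + 7.9 * dnorm(13.4 / 7.9) / pnorm(13.4 / 7.9)
  expect_equal(mean(ct$choline), mu_trunc, tolerance = 0.01)
  expect_true(all(ct$choline >= 0))
})

test_that("default cohort matches the clinical design and is uncorrelated", {
  co <- simulate_cohort(seed = 1)
  expect_equal(table(co$group)[["non-PCa"]], 10)
  expect_equal(table(co$group)[["PCa"]], 16)
  expect_named(co, c("sample_id", "group", "LAA", "glutamate", "choline",
                     "sarcosine"))
  # metabolites are generated independently: mean |off-diagonal correlation|
  # over seeds stays well below the 0.3 screen
  cors <- sapply(1:30, function(s) {
    cc <- attr(univariate_summary(simulate_cohort(seed = s)),
               "cross_correlation")
    mean(abs(cc[upper.tri(cc)]))
  })
  expect_lt(mean(cors), 0.3)
})

test_that("calibration series follow the true curve with relative noise", {
  grid <- c(0, 300, 600, 900, 1200, 1500)
  tab0 <- make_calibration_series("LAA", grid, replicates = 3,
                                  noise_rel = 0, seed = 1)
  expect_equal(tab0$rate_mV_per_s,
               oracle_mm(tab0$concentration_uM, 3.63, 2866, -0.032),
               tolerance = 1e-12)
  # Monte-Carlo: per-point relative SD ~ noise_rel (scaled-down: 80 seeds)
  rel <- unlist(lapply(1:80, function(s) {
    tb <- make_calibration_series("LAA", c(600, 1200), replicates = 3,
                                  noise_rel = 0.18, seed = s)
    truth <- oracle_mm(tb$concentration_uM, 3.63, 2866, -0.032)
    tb$rate_mV_per_s / truth - 1
  }))
  expect_equal(sd(rel), 0.18, tolerance = 0.1)
  # all-zero concentrations: rates sit at the curve's zero-substrate value
  tbz <- make_calibration_series("LAA", c(0, 0, 0), replicates = 2,
                                 noise_rel = 0.18, seed = 3)
  expect_true(all(abs(tbz$rate_mV_per_s - (-0.032)) < 0.05))
})

test_that("extracted negative-control rates match the configured statistics", {
  # invariant run at 100 seeds, 60-s acquisitions on a single-channel map
  # (full 300-s four-channel runs would be ~20x slower with the same check)
  map1 <- one_channel_map()
  ctrl <- panel_kinetics("control", pm)
  rates <- vapply(1:100, function(s) {
    st <- simulate_frame_stack(0, list(ctrl),
                               map = map1,
                               sm = sensor_model(dead_fraction = 0),
                               pm = pm, duration = 60, seed = 1000 + s)
    extract_rate(st, map1)$rate_mV_per_s * 1000
  }, numeric(1))
  se_mean <- 2.7 / sqrt(100)
  se_sd <- 2.7 / sqrt(2 * 99)
  expect_lt(abs(mean(rates) - 5.0), 3 * se_mean)
  expect_lt(abs(sd(rates) - 2.7), 3 * se_sd)
})
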