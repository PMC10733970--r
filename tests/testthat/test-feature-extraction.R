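make_bump_trace <- function(centers, amp = 60, width = 2, dt = 0.1,
                            t_stop = 400, base = -65) {
  t <- seq(0, t_stop, by = dt)
  v <- rep(base, length(t))
  for (c0 in centers) v <- v + amp * exp(-((t - c0)^2) / (2 * width^2))
  voltage_trace(t, v, meta = list(amplitude_nA = 0.3, delay_ms = 50,
                                  duration_ms = 300))
}

test_that("spike detection finds one peak per suprathreshold window", {
  tr <- make_bump_trace(c(100, 200, 300))
  expect_equal(detect_spikes(tr), c(100, 200, 300))
  sub <- make_bump_trace(numeric(0))
  expect_identical(detect_spikes(sub), numeric(0))
  # double-peaked window: a single spike at the higher peak
  t <- seq(0, 100, by = 0.1)
  v <- -65 + 50 * exp(-((t - 40)^2) / 8) + 55 * exp(-((t - 44)^2) / 8)
  v <- pmax(v, ifelse(t > 40 & t < 44, -10, -65)) # keep window contiguous
  tr2 <- voltage_trace(t, v)
  st <- detect_spikes(tr2)
  expect_length(st, 1)
  expect_equal(st, t[which.max(v)])
  # time-shift invariance
  tr3 <- voltage_trace(tr$t_ms + 17, tr$v_mV)
  expect_equal(detect_spikes(tr3), detect_spikes(tr) + 17)
})

test_that("timing features follow the stated conventions", {
  f <- timing_features(c(120, 170), onset = 100, duration = 400)
  expect_equal(f$spikecount_stimint, 2)
  expect_equal(f$time_to_first_spike, 20)
  expect_equal(f$inv_first_ISI, 1000 / 50)
  expect_true(is.na(f$inv_second_ISI))
  # 8 spikes in 400 ms -> 20 Hz
  f8 <- timing_features(seq(110, 460, by = 50), 100, 400)
  expect_equal(f8$mean_frequency, 20)
  # one spike: ISIs absent, not zero
  f1 <- timing_features(150, 100, 400)
  expect_true(is.na(f1$inv_first_ISI) && is.na(f1$inv_last_ISI))
  expect_equal(f1$spikecount_stimint, 1)
  # spikes outside the window are not counted
  fo <- timing_features(c(50, 150, 600), 100, 400)
  expect_equal(fo$spikecount_stimint, 1)
})

test_that("adaptation index matches its definition", {
  expect_equal(adaptation_index(seq(0, 100, by = 10)), 0)
  # ISIs 10, 12, 14: (2/22 + 2/26) / 2
  expect_equal(adaptation_index(c(0, 10, 22, 36)), (2/22 + 2/26) / 2,
               tolerance = 1e-12)
  expect_equal(adaptation_index(-rev(c(0, 10, 22, 36))),
               -(2/22 + 2/26) / 2, tolerance = 1e-12)
  expect_true(is.na(adaptation_index(c(1, 2))))
  # bounded in (-1, 1)
  expect_lt(abs(adaptation_index(c(0, 1, 100, 101, 300))), 1)
})

test_that("AP shape features are measured at the -20 mV threshold", {
  # triangular pulse from -60 to +20, crossing -20 for exactly 2 ms
  dt <- 0.001
  t <- seq(0, 10, by = dt)
  up <- 80 # mV/ms rise and fall
  v <- pmax(-60, 20 - up * abs(t - 5))
  tr <- voltage_trace(t, v)
  sh <- shape_features(tr)
  expect_equal(sh$AP_width, 2 * 40 / up, tolerance = 1e-3)
  expect_equal(sh$AP_amplitude, 20 - (-20))
  # phase plot of a sinusoid: max |dv/dt| = A * omega
  A <- 30
  f_khz <- 1 / 20 # period 20 ms
  ts <- seq(0, 100, by = 0.05)
  vs <- -40 + A * sin(2 * pi * f_khz * ts)
  ph <- shape_features(voltage_trace(ts, vs))$phase_plot
  expect_equal(max(abs(ph$dvdt), na.rm = TRUE), A * 2 * pi * f_khz,
               tolerance = 0.01)
  # spike truncated at the trace edge yields NA
  vtr <- seq(10, -60, length.out = 50) # starts suprathreshold
  tr_edge <- voltage_trace(seq_along(vtr) * 0.1, vtr)
  sh2 <- shape_features(tr_edge)
  expect_true(is.na(sh2$AP_width))
})

test_that("subthreshold features decompose the hyperpolarizing response", {
  dt <- 0.1
  t <- seq(0, 600, by = dt)
  v <- rep(-65, length(t))
  stim <- t >= 100 & t <= 500
  ts <- t[stim] - 100
  v[stim] <- -75 - 5 * exp(-ts / 60) * (ts > 50) - # decays back: sag
    15 * (1 - exp(-ts / 10)) * (ts <= 50) - 15 * (ts > 50) * exp(-(ts - 50) / 60)
  # simpler constructed case instead: piecewise with known min and steady
  v <- rep(-65, length(t))
  v[stim] <- -75 + 0 * ts
  v[t >= 150 & t <= 250] <- -80
  tr <- voltage_trace(t, v, meta = list())
  s <- subthreshold_features(tr, 100, 400)
  expect_equal(s$voltage_base, -65)
  expect_equal(s$steady_state_voltage, -75)
  expect_equal(s$voltage_deflection, -10)
  expect_equal(s$sag_amplitude, 5)
  # flat trace: zero sag
  flat <- voltage_trace(t, rep(-65, length(t)))
  sf <- subthreshold_features(flat, 100, 400)
  expect_equal(sf$sag_amplitude, 0)
  expect_equal(sf$voltage_deflection, 0)
  expect_error(subthreshold_features(flat, 500, 400), "outside")
  # sag is never negative, even for depolarizing steps
  vd <- rep(-65, length(t)); vd[stim] <- -55
  expect_gte(subthreshold_features(voltage_trace(t, vd), 100,
                                   400)$sag_amplitude, 0)
})

test_that("membrane time constant is recovered from the initial decay", {
  dt <- 0.05
  t <- seq(0, 500, by = dt)
  v <- rep(-65, length(t))
  stim <- t >= 100
  v[stim] <- -75 + 10 * exp(-(t[stim] - 100) / 15)
  tr <- voltage_trace(t, v)
  expect_equal(membrane_time_constant(tr, 100, 400), 15, tolerance = 0.01)
  # robust to 0.1 mV noise within 5%
  for (seed in 1:3) {
    trn <- tr
    trn$v_mV <- trn$v_mV + with_local_seed(seed,
      rnorm(length(v), 0, 0.1))
    expect_equal(membrane_time_constant(trn, 100, 400), 15,
                 tolerance = 0.05)
  }
  vd <- rep(-65, length(t)); vd[stim] <- -55
  expect_error(membrane_time_constant(voltage_trace(t, vd), 100, 400),
               "hyperpolarizing")
})

test_that("input resistance uses the smallest negative injection", {
  mk <- function(amp, defl) {
    t <- seq(0, 600, by = 0.5)
    v <- rep(-65, length(t))
    v[t >= 100 & t <= 500] <- -65 + defl
    voltage_trace(t, v, meta = list(amplitude_nA = amp, delay_ms = 100,
                                    duration_ms = 400))
  }
  expect_equal(input_resistance(list(mk(-0.05, -5))), 100)
  # two negatives: the smaller magnitude (-0.05) is selected
  expect_equal(input_resistance(list(mk(-0.2, -30), mk(-0.05, -5))), 100)
  expect_error(input_resistance(list(mk(0.1, 10))), "negative")
  # closed form on the RC cell: Rin = 1/g = 100 MOhm
  cell <- inject_step_current(rc_cell(), "soma", -0.05, 100, 400)
  tr <- simulate(cell, sim_config(t_stop = 600),
                 meta = list(amplitude_nA = -0.05, delay_ms = 100,
                             duration_ms = 400))
  expect_equal(input_resistance(list(tr)), 100, tolerance = 0.01)
})

test_that("trend and group statistics behave on constructed data", {
  df <- data.frame(cell = rep(1:2, each = 3),
                   species = "mouse",
                   amplitude = rep(c(0.1, 0.2, 0.3), 2),
                   value = rep(c(1, 2, 3), 2))
  res <- trend_and_group_stats(df)
  expect_equal(unname(res$slopes[["mouse"]]), 10)
  # identical groups: rank-sum p ~ 1
  df2 <- data.frame(cell = 1:12, species = rep(c("mouse", "rat"), 6),
                    amplitude = 0.2, value = rep(c(1, 2, 3), 4))
  res2 <- trend_and_group_stats(df2)
  expect_gt(res2$comparisons$p_value[1], 0.5)
  # well-separated Gaussians: tiny p
  set.seed(1)
  df3 <- data.frame(cell = 1:80, species = rep(c("mouse", "rat"), each = 40),
                    amplitude = 0.2,
                    value = c(rnorm(40, 0, 1), rnorm(40, 5, 1)))
  res3 <- trend_and_group_stats(df3)
  expect_lt(res3$comparisons$p_value[1], 1e-6)
})

test_that("extract_features assembles the full panel", {
  tr <- make_bump_trace(c(100, 150, 210, 280))
  fx <- extract_features(tr)
  expect_equal(fx$spikecount_stimint, 4)
  expect_equal(fx$inv_first_ISI, 20)
  expect_false(is.na(fx$adaptation_index))
  expect_true(all(c("voltage_base", "sag_amplitude", "AP_width")
                  %in% names(fx)))
  expect_error(extract_features(voltage_trace(1:3, rep(-65, 3))),
               "metadata")
})
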