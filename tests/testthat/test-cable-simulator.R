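test_that("passive RC response matches the closed form", {
  cell <- inject_step_current(rc_cell(), "soma", 0.1, 50, 100)
  tr <- simulate(cell, sim_config(t_stop = 200, dt = 0.025))
  sel <- tr$t_ms >= 50 & tr$t_ms <= 150
  pred <- -70 + 10 * (1 - exp(-(tr$t_ms[sel] - 50) / 10))
  expect_lt(max(abs(tr$v_mV[sel] - pred)), 0.005 * 10) # within 0.5%
  # steady deflection obeys Ohm's law: -0.2 nA * 100 MOhm
  c2 <- inject_step_current(rc_cell(), "soma", -0.2, 10, 150)
  tr2 <- simulate(c2, sim_config(t_stop = 170, dt = 0.025))
  expect_equal(tr2$v_mV[tr2$t_ms == 155] - (-70), -0.2 * 100,
               tolerance = 1e-3)
})

test_that("temporal convergence of the Crank-Nicolson solve is second order", {
  err <- sapply(c(0.1, 0.05, 0.025), function(dt) {
    cell <- inject_step_current(rc_cell(), "soma", 0.1, 0, 100)
    tr <- simulate(cell, sim_config(t_stop = 100, dt = dt))
    keep <- abs(tr$t_ms %% 1) < 1e-9 & tr$t_ms > 0
    pred <- -70 + 10 * (1 - exp(-tr$t_ms[keep] / 10))
    max(abs(tr$v_mV[keep] - pred))
  })
  order1 <- log2(err[1] / err[2])
  order2 <- log2(err[2] / err[3])
  expect_gt(order1, 1.8)
  expect_gt(order2, 1.8)
})

test_that("implicit Euler is available and first-order accurate", {
  err <- sapply(c(0.1, 0.05), function(dt) {
    cell <- inject_step_current(rc_cell(), "soma", 0.1, 0, 100)
    tr <- simulate(cell, sim_config(t_stop = 100, dt = dt,
                                    method = "implicit_euler"))
    keep <- abs(tr$t_ms %% 1) < 1e-9 & tr$t_ms > 0
    pred <- -70 + 10 * (1 - exp(-tr$t_ms[keep] / 10))
    max(abs(tr$v_mV[keep] - pred))
  })
  expect_gt(log2(err[1] / err[2]), 0.8)
  expect_lt(log2(err[1] / err[2]), 1.5)
})

test_that("steady-state attenuation along a passive cable is exponential", {
  # uniform cable, d = 2 um, Rm = 10 kOhm cm2, Ra = 150 Ohm cm:
  # lambda = sqrt((d/4) * Rm/Ra) ~ 408 um; 5-lambda sealed cable
  n <- 100
  seg <- 20
  d <- 2
  comps <- data.frame(
    comp = seq_len(n), section = "cable", region = "apical_trunk",
    pos = (seq_len(n) - 0.5) / n, length_um = seg, diam_um = d,
    area_cm2 = pi * d * seg * 1e-8,
    r_axial_unit = seg / (pi * (d / 2)^2) * 1e-2,
    path_dist_um = (seq_len(n) - 0.5) * seg,
    parent_comp = c(NA, seq_len(n - 1)))
  comps$region[1] <- "soma" # record site bookkeeping only
  cell <- assemble(comps, matrix(numeric(0), n, 0), list(),
                   passive = list(g_pas = 1e-4, e_pas = -70, cm = 1,
                                  Ra = 150), ca_pool = NULL)
  cell <- inject_step_current(cell, 1, -0.05, 0, 1500)
  res <- simulate(cell, sim_config(t_stop = 1500, dt = 0.1,
                                   record = seq_len(n)))
  vss <- vapply(res, function(tr) tr$v_mV[length(tr$v_mV)], numeric(1))
  defl <- vss - (-70)
  lambda <- sqrt((d * 1e-4 / 4) * (1 / 1e-4) / 150) * 1e4 # um
  x <- comps$path_dist_um - comps$path_dist_um[1]
  sel <- x <= 2 * lambda
  ratio <- defl[sel] / defl[1]
  expect_lt(max(abs(ratio - exp(-x[sel] / lambda))), 0.02)
})

test_that("a cell initialized at its resting fixed point stays at rest", {
  cell <- cached("mouse_preset", cell_preset("mouse"))
  long <- simulate(cell, sim_config(t_stop = 100, settle_ms = 4000))
  rest <- long$v_mV[length(long$v_mV)]
  tr <- simulate(cell, sim_config(t_stop = 1000, v_init = rest,
                                  settle_ms = 2000))
  expect_lt(max(abs(tr$v_mV - rest)), 0.01)
})

test_that("step currents superpose linearly in a passive cell", {
  one <- inject_step_current(rc_cell(), "soma", 0.2, 20, 60)
  two <- inject_step_current(
    inject_step_current(rc_cell(), "soma", 0.1, 20, 60),
    "soma", 0.1, 20, 60)
  t1 <- simulate(one, sim_config(t_stop = 100))
  t2 <- simulate(two, sim_config(t_stop = 100))
  expect_equal(t1$v_mV, t2$v_mV, tolerance = 1e-12)
  # zero amplitude leaves the trajectory untouched
  z <- inject_step_current(rc_cell(), "soma", 0, 20, 60)
  tz <- simulate(z, sim_config(t_stop = 100))
  t0 <- simulate(rc_cell(), sim_config(t_stop = 100))
  expect_identical(tz$v_mV, t0$v_mV)
  expect_error(inject_step_current(rc_cell(), 99, 0.1, 0, 10), "site")
})

test_that("the double-exponential synapse is peak-normalized", {
  # quasi-voltage-clamp: huge capacitance pins v, so C dv/dt tracks g(E - v)
  cell <- single_compartment_cell(C_pF = 1e5, g_leak_nS = 0.001,
                                  e_leak = -70)
  w <- 0.5 # nS
  cell <- attach_double_exp_synapse(cell, "soma", tau_rise = 0.5,
                                    tau_decay = 3, weight = w,
                                    reversal = 0, spike_times = 10)
  tr <- simulate(cell, sim_config(t_stop = 30, dt = 0.01))
  dvdt <- diff(tr$v_mV) / 0.01            # mV/ms
  i_nA <- dvdt * 1e5 * 1e-3               # C in nF = 100
  g_nS <- i_nA / (0 - (-70)) * 1e3        # nA / mV -> uS -> nS
  expect_equal(max(g_nS), w, tolerance = 0.02)
  tpk <- tr$t_ms[which.max(c(0, g_nS))] - 10
  tpk_theory <- (0.5 * 3) / (3 - 0.5) * log(3 / 0.5)
  expect_equal(tpk, tpk_theory, tolerance = 0.05)
})

test_that("synaptic responses saturate against the driving force", {
  mk <- function(times, w = 2) {
    cell <- attach_double_exp_synapse(rc_cell(), "soma", weight = w,
                                      reversal = 0, spike_times = times)
    simulate(cell, sim_config(t_stop = 60))
  }
  single1 <- mk(10)
  single2 <- mk(15)
  both <- mk(c(10, 15))
  lin <- single1$v_mV + single2$v_mV - (-70) * 2 + (-70)
  expect_true(all(both$v_mV <= lin + 1e-9))
  expect_lt(max(both$v_mV), max(lin))
  # weight 0 leaves the cell flat
  flat <- mk(10, w = 0)
  expect_equal(flat$v_mV, rep(-70, length(flat$v_mV)), tolerance = 1e-9)
  expect_error(attach_double_exp_synapse(rc_cell(), "soma", tau_rise = 3,
                                         tau_decay = 1, weight = 1,
                                         spike_times = 1), "tau")
})

test_that("spatial refinement leaves the somatic trace nearly unchanged", {
  for (seg in c(20, 10)) {
    cell <- cell_preset("mouse", max_seg_um = seg)
    cell <- inject_step_current(cell, "soma", -0.1, 50, 300)
    tr <- simulate(cell, sim_config(t_stop = 400, dt = 0.05,
                                    settle_ms = 500))
    if (seg == 20) v20 <- tr$v_mV else v10 <- tr$v_mV
  }
  rms <- sqrt(mean((v20 - v10)^2))
  expect_lt(rms / diff(range(v10)), 0.01)
})

test_that("assembly validates its inputs", {
  comps <- discretize(build_reduced_morphology("mouse"))
  dens <- matrix(1e-4, 3, 1, dimnames = list(NULL, "KDR"))
  expect_error(assemble(comps, dens, default_channel_library("mouse")),
               "cover every compartment")
  dens2 <- matrix(1e-4, nrow(comps), 1, dimnames = list(NULL, "Mystery"))
  expect_error(assemble(comps, dens2, default_channel_library("mouse")),
               "unknown channel")
  cfg <- sim_config(t_stop = 10, record = 1e6)
  cell <- cell_preset("mouse")
  expect_error(simulate(cell, cfg), "site")
  expect_error(sim_config(t_stop = 1, dt = -1))
})
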