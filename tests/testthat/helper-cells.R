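# Shared light fixtures. Anything simulation-heavy is built lazily and
# cached for the session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# passive RC cell: C = 100 pF, g = 10 nS, tau = 10 ms, Rin = 100 MOhm
rc_cell <- function(...) single_compartment_cell(C_pF = 100, g_leak_nS = 10,
                                                 e_leak = -70, ...)

# tiny hand-built morphology: soma + one 10 um apical section
toy_swc <- function() {
  f <- tempfile(fileext = ".swc")
  writeLines(c("# toy",
               "1 1 0 0 0 5 -1",
               "2 4 10 0 0 1 1"), f)
  f
}

# a three-compartment table used for synapse-placement filtering tests
placement_comps <- function() {
  data.frame(comp = 1:3, section = c("obl1", "obl2", "obl3"),
             region = "oblique", pos = 0.5, length_um = 50,
             diam_um = c(0.8, 1.1, 0.9), area_cm2 = 1e-6,
             r_axial_unit = 1, path_dist_um = c(100, 200, 350),
             parent_comp = c(NA, 1L, 2L))
}

make_hyperpol_traces <- function(species = "mouse", noise_sd = 0.1,
                                 seed = 1, gbar_ih = 1e-4,
                                 amps = c(-0.05, -0.1, -0.15, -0.2)) {
  ih <- make_ih_preset(species)
  cell <- single_compartment_cell(C_pF = 150, g_leak_nS = 6, e_leak = -70,
                                  ih = ih, gbar_ih = gbar_ih)
  lapply(seq_along(amps), function(k) {
    c2 <- inject_step_current(cell, "soma", amps[k], 100, 800)
    tr <- simulate(c2, sim_config(t_stop = 1000, settle_ms = 500),
                   meta = list(amplitude_nA = amps[k], delay_ms = 100,
                               duration_ms = 800))
    if (noise_sd > 0)
      tr$v_mV <- tr$v_mV + with_local_seed(seed + k,
        rnorm(length(tr$v_mV), 0, noise_sd))
    tr
  })
}
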