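## Assembly of simulatable cells and the deterministic cable solve.

#' Simulation configuration
#'
#' @param dt Time step (ms); default 0.025.
#' @param t_stop Simulation end (ms).
#' @param v_init Initial voltage (mV); default -70.
#' @param method `"crank_nicolson"` (default) or `"implicit_euler"`.
#' @param record Compartment ids to record, or `"soma"`.
#' @param settle_ms Unrecorded settling time before t = 0 (gates and voltage
#'   relax toward rest); default 0.
#' @return A `sim_config` object.
#' @export
sim_config <- function(t_stop, dt = 0.025, v_init = -70,
                       method = c("crank_nicolson", "implicit_euler"),
                       record = "soma", settle_ms = 0) {
  method <- match.arg(method)
  if (dt <= 0 || t_stop < dt) stop("need dt > 0 and t_stop >= dt")
  structure(list(dt = dt, t_stop = t_stop, v_init = v_init, method = method,
                 record = record, settle_ms = settle_ms),
            class = "sim_config")
}

#' Assemble a simulatable cell
#'
#' Binds geometry, channel kinetics, per-compartment densities, passive
#' properties and the calcium pool into one object accepted by [simulate()].
#'
#' @param morph A `morphology` (discretized internally) or a compartment
#'   table from [discretize()].
#' @param density Matrix (compartments x channels) from
#'   [apply_distributions()]; every referenced channel must exist in
#'   `channels`.
#' @param channels Named list of [channel_spec()] objects.
#' @param passive List with `g_pas` (S/cm2, scalar or per-compartment),
#'   `e_pas` (mV), `cm` (uF/cm2), `Ra` (Ohm*cm).
#' @param ca_pool A [calcium_pool()] or NULL to disable calcium dynamics.
#' @param max_seg_um Spatial discretization bound when `morph` is a
#'   morphology.
#' @return A `cable_cell` object.
#' @export
assemble <- function(morph, density, channels,
                     passive = list(g_pas = 1e-4, e_pas = -65, cm = 1,
                                    Ra = 150),
                     ca_pool = calcium_pool(), max_seg_um = 20) {
  comps <- if (inherits(morph, "morphology")) discretize(morph, max_seg_um)
           else morph
  if (nrow(density) != nrow(comps))
    stop("density map does not cover every compartment")
  missing <- setdiff(colnames(density), names(channels))
  if (length(missing))
    stop("density references unknown channel(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(comps)
  g_pas <- rep_len(passive$g_pas, n)
  cm <- rep_len(passive$cm, n)
  structure(list(comps = comps, density = density,
                 channels = channels[colnames(density)],
                 g_pas = g_pas, e_pas = rep_len(passive$e_pas, n), cm = cm,
                 Ra = passive$Ra, ca_pool = ca_pool,
                 stimuli = list(), synapses = list()),
            class = "cable_cell")
}

#' @export
print.cable_cell <- function(x, ...) {
  cat(sprintf("cable_cell: %d compartments, %d channels, %d stimuli, %d synapses\n",
              nrow(x$comps), ncol(x$density), length(x$stimuli),
              length(x$synapses)))
  invisible(x)
}

#' Soma compartment id of a cell
#' @param cell A `cable_cell`.
#' @return Integer compartment id.
#' @export
soma_comp <- function(cell) which(cell$comps$region == "soma")[1]

#' Add a step current clamp
#'
#' @param cell A `cable_cell`.
#' @param site Compartment id or `"soma"`.
#' @param amplitude Current (nA).
#' @param delay Onset (ms).
#' @param duration Duration (ms).
#' @return The modified cell.
#' @export
inject_step_current <- function(cell, site = "soma", amplitude, delay,
                                duration) {
  comp <- if (identical(site, "soma")) soma_comp(cell) else as.integer(site)
  if (is.na(comp) || comp < 1 || comp > nrow(cell$comps))
    stop("unknown injection site")
  cell$stimuli[[length(cell$stimuli) + 1L]] <-
    list(comp = comp, amp_nA = amplitude, delay = delay, duration = duration)
  cell
}

#' Attach a double-exponential conductance synapse
#'
#' Conductance time course is the peak-normalized difference of exponentials:
#' a single spike of weight `w` reaches peak conductance exactly `w` at
#' `t_peak = tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`.
#' Multiple spikes superpose linearly in the two state variables.
#'
#' @param cell A `cable_cell`.
#' @param site Compartment id or `"soma"`.
#' @param tau_rise,tau_decay Time constants (ms), `tau_decay > tau_rise > 0`.
#' @param weight Peak conductance (nS).
#' @param reversal Synaptic reversal (mV); default 0 (AMPA).
#' @param spike_times Presynaptic spike times (ms).
#' @return The modified cell.
#' @export
attach_double_exp_synapse <- function(cell, site, tau_rise = 0.5,
                                      tau_decay = 3, weight, reversal = 0,
                                      spike_times) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("need tau_decay > tau_rise > 0")
  if (weight < 0) stop("weight must be >= 0")
  comp <- if (identical(site, "soma")) soma_comp(cell) else as.integer(site)
  if (is.na(comp) || comp < 1 || comp > nrow(cell$comps))
    stop("unknown synapse site")
  cell$synapses[[length(cell$synapses) + 1L]] <-
    list(comp = comp, tau_rise = tau_rise, tau_decay = tau_decay,
         weight_nS = weight, reversal = reversal,
         times = as.numeric(spike_times))
  cell
}

## serialize a channel_spec into the flat structure the C++ engine reads
.gate_to_engine <- function(g) {
  p <- g$parameters
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  params <- switch(g$form,
    borg_graham = c(p$vhalf_l, p$vhalf_t, p$a0t, p$zeta_l, p$zeta_t, p$gmt,
                    num(p$temperature_factor, 1), num(p$kT, .kT_DEFAULT)),
    alpha_beta = c(p$a_form, p$a_rate, p$a_vhalf, p$a_slope,
                   p$b_form, p$b_rate, p$b_vhalf, p$b_slope,
                   num(p$tau_min, 0)),
    inf_tau = c(p$vhalf, p$slope, p$tau_min, p$tau_amp, p$tau_vhalf,
                p$tau_slope),
    calcium_hill = c(p$n, p$khalf_mM, p$tau_ms, num(p$vslope, 0),
                     num(p$vref, -20)))
  list(form = match(g$form, .GATE_FORMS) - 1L, power = g$power,
       params = as.numeric(params))
}

.cell_to_engine <- function(cell) {
  comps <- cell$comps
  n <- nrow(comps)
  g_ax <- numeric(n)
  for (i in seq_len(n)) {
    p <- comps$parent_comp[i]
    if (is.na(p)) next
    r <- cell$Ra * (comps$r_axial_unit[i] + comps$r_axial_unit[p]) / 2
    g_ax[i] <- 1 / r
  }
  chans <- lapply(names(cell$channels), function(nm) {
    sp <- cell$channels[[nm]]
    list(name = nm, reversal = sp$reversal,
         ca_flux = sp$calcium_flux_fraction,
         density = as.numeric(cell$density[, nm]),
         gates = lapply(sp$gates, .gate_to_engine))
  })
  cp <- cell$ca_pool
  list(parent = ifelse(is.na(comps$parent_comp), 0L,
                       as.integer(comps$parent_comp)),
       area_cm2 = comps$area_cm2, cm_uF = cell$cm, g_axial_uS = g_ax,
       g_pas = cell$g_pas, e_pas = cell$e_pas, channels = chans,
       ca_pool = list(present = !is.null(cp),
                      decay_tau = if (is.null(cp)) 100 else cp$decay_tau,
                      rest = if (is.null(cp)) 0 else cp$resting_concentration,
                      gain = if (is.null(cp)) 0
                             else cp$current_to_concentration_gain),
       stimuli = cell$stimuli, synapses = cell$synapses)
}

#' Run a simulation
#'
#' Deterministic given the cell, the configuration and the attached stimuli.
#'
#' @param cell A `cable_cell`.
#' @param config A [sim_config()].
#' @param meta Optional stimulus metadata attached to the returned trace
#'   (protocol, amplitude...); defaults are derived from the first step
#'   stimulus.
#' @return A `voltage_trace` (single record site) or a list of them.
#' @export
simulate <- function(cell, config, meta = list()) {
  rec <- if (identical(config$record, "soma")) soma_comp(cell)
         else as.integer(config$record)
  if (any(is.na(rec)) || any(rec < 1) || any(rec > nrow(cell$comps)))
    stop("recorded site does not exist")
  engine_cfg <- list(dt = config$dt, t_stop = config$t_stop,
                     v_init = config$v_init,
                     theta = if (config$method == "crank_nicolson") 0.5 else 1,
                     settle_ms = config$settle_ms, record_comps = rec)
  res <- .cable_run(.cell_to_engine(cell), engine_cfg)
  base_meta <- if (length(cell$stimuli))
    list(amplitude_nA = cell$stimuli[[1]]$amp_nA,
         delay_ms = cell$stimuli[[1]]$delay,
         duration_ms = cell$stimuli[[1]]$duration)
  else list()
  meta <- utils::modifyList(base_meta, meta)
  traces <- lapply(seq_along(rec), function(j)
    voltage_trace(res$t, res$v[, j], meta))
  if (length(traces) == 1L) traces[[1]] else traces
}

#' Voltage trace container
#'
#' @param t_ms Uniform time base (ms).
#' @param v_mV Voltage samples (mV).
#' @param meta Named list of stimulus metadata (amplitude_nA, delay_ms,
#'   duration_ms, protocol, cell_id, species).
#' @return A `voltage_trace` object.
#' @export
voltage_trace <- function(t_ms, v_mV, meta = list()) {
  if (length(t_ms) != length(v_mV)) stop("time/voltage length mismatch")
  if (any(diff(t_ms) <= 0)) stop("time must be strictly increasing")
  structure(list(t_ms = as.numeric(t_ms), v_mV = as.numeric(v_mV),
                 meta = meta),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage_trace: %d samples over %.1f ms, range [%.1f, %.1f] mV\n",
              length(x$t_ms), max(x$t_ms), min(x$v_mV), max(x$v_mV)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Single-compartment cell with given total capacitance and leak
#'
#' Convenience constructor used by tests and the h-current prefit: an
#' isopotential cell with total capacitance `C_pF`, leak `g_leak_nS` and
#' optionally an Ih channel.
#'
#' @param C_pF Total capacitance (pF).
#' @param g_leak_nS Leak conductance (nS).
#' @param e_leak Leak reversal (mV).
#' @param ih A [channel_spec()] for Ih, or NULL.
#' @param gbar_ih Ih peak density (S/cm2).
#' @return A `cable_cell`.
#' @export
single_compartment_cell <- function(C_pF = 100, g_leak_nS = 10,
                                    e_leak = -70, ih = NULL, gbar_ih = 0) {
  area <- C_pF * 1e-3 / 1e3            # nF / (1e3 nF per uF/cm2) -> cm2
  g_pas <- g_leak_nS * 1e-9 / area     # S / cm2
  comps <- data.frame(comp = 1L, section = "soma", region = "soma",
                      pos = 0.5, length_um = 10, diam_um = 10,
                      area_cm2 = area, r_axial_unit = 1,
                      path_dist_um = 0, parent_comp = NA_integer_,
                      stringsAsFactors = FALSE)
  if (is.null(ih)) {
    dens <- matrix(numeric(0), 1, 0)
    chans <- list()
  } else {
    dens <- matrix(gbar_ih, 1, 1, dimnames = list(NULL, "Ih"))
    chans <- list(Ih = ih)
  }
  assemble(comps, dens, chans,
           passive = list(g_pas = g_pas, e_pas = e_leak, cm = 1, Ra = 150),
           ca_pool = NULL)
}
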