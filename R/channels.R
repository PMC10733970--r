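## Declarative membrane-conductance kinetics.
##
## Gate forms supported:
##   borg_graham  - thermodynamic gating with effective charges (zeta), an
##                  asymmetry factor (gmt) and a rate scale (a0t)
##   alpha_beta   - classic HH rate-function pairs (exponential / sigmoid /
##                  linoid forms)
##   inf_tau      - direct sigmoid steady state with a bell-shaped time
##                  constant
##   calcium_hill - Hill function of pool calcium, optionally voltage-shifted
##
## The h-current (Ih) is the only channel whose kinetic parameters are
## species-specific; both presets ship with the package.

#' Borg-Graham gating parameters
#'
#' Container for the thermodynamic gating model in which voltage dependence
#' enters through effective gating charges. `vhalf_l` / `zeta_l` control the
#' steady-state activation curve, `vhalf_t` / `zeta_t` / `gmt` / `a0t` control
#' the voltage-dependent time constant. `clk` is an auxiliary scale reported
#' by the fitted h-current model; by default it does not enter the rate
#' equations (see `clk_mode`).
#'
#' @param vhalf_l Steady-state half-activation voltage (mV).
#' @param vhalf_t Time-constant midpoint voltage (mV).
#' @param a0t Rate scale (1/ms); must be positive.
#' @param zeta_l Steady-state slope charge (dimensionless). Positive values
#'   give activation by hyperpolarization (as for Ih).
#' @param zeta_t Rate slope charge (dimensionless).
#' @param gmt Rate asymmetry factor, in (0, 1).
#' @param clk Auxiliary scale; stored and reported, inert unless
#'   `clk_mode = "divide_a0t"`.
#' @param temperature_factor Lumped q-factor multiplying the rates; default 1.
#' @param kT Thermodynamic slope F/(RT) per mV; default 0.0378 (33 C).
#' @param clk_mode Either `"inert"` (default) or `"multiply_a0t"`, in which
#'   case the effective rate scale becomes `a0t * clk`. With the shipped
#'   values (clk 0.24 mouse, 1 rat) the multiplicative reading slows the
#'   mouse gate about 4-fold relative to rat, which is the only convention
#'   consistent with the reported species difference; it stays opt-in
#'   because the source model never prints the equation clk enters.
#' @return An object of class `bg_params`.
#' @export
bg_params <- function(vhalf_l, vhalf_t, a0t, zeta_l, zeta_t, gmt,
                      clk = 1, temperature_factor = 1, kT = .kT_DEFAULT,
                      clk_mode = c("inert", "multiply_a0t")) {
  clk_mode <- match.arg(clk_mode)
  stopifnot(is.numeric(vhalf_l), is.numeric(vhalf_t), length(vhalf_l) == 1L)
  if (!is.finite(a0t) || a0t <= 0) stop("a0t must be > 0")
  if (!is.finite(temperature_factor) || temperature_factor <= 0)
    stop("temperature_factor must be > 0")
  if (!is.finite(gmt) || gmt <= 0 || gmt >= 1) stop("gmt must lie in (0,1)")
  structure(list(vhalf_l = vhalf_l, vhalf_t = vhalf_t, a0t = a0t,
                 zeta_l = zeta_l, zeta_t = zeta_t, gmt = gmt, clk = clk,
                 temperature_factor = temperature_factor, kT = kT,
                 clk_mode = clk_mode),
            class = "bg_params")
}

#' @export
print.bg_params <- function(x, ...) {
  cat("Borg-Graham gate parameters\n")
  cat(sprintf("  vhalf_l %.3f mV  zeta_l %.3f\n", x$vhalf_l, x$zeta_l))
  cat(sprintf("  vhalf_t %.3f mV  zeta_t %.3f  gmt %.3f  a0t %.3g /ms\n",
              x$vhalf_t, x$zeta_t, x$gmt, x$a0t))
  cat(sprintf("  clk %.3g (%s)  temperature_factor %.3g\n",
              x$clk, x$clk_mode, x$temperature_factor))
  invisible(x)
}

.bg_check_v <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v))) stop("voltage must be finite")
  v
}

#' Steady-state activation of a Borg-Graham gate
#'
#' Evaluates `1 / (1 + exp(kT * zeta_l * (v - vhalf_l)))`. With positive
#' `zeta_l` the curve decreases with voltage, i.e. the gate is opened by
#' hyperpolarization (the h-current convention).
#'
#' @param v Membrane voltage (mV), vectorized.
#' @param p A [bg_params()] object.
#' @return Activation in \[0, 1\].
#' @export
bg_steady_state <- function(v, p) {
  stopifnot(inherits(p, "bg_params"))
  v <- .bg_check_v(v)
  1 / (1 + exp(p$kT * p$zeta_l * (v - p$vhalf_l)))
}

#' Voltage-dependent time constant of a Borg-Graham gate
#'
#' Evaluates
#' `exp(kT*zeta_t*gmt*(v - vhalf_t)) / (tf * a0 * (1 + exp(kT*zeta_t*(v - vhalf_t))))`
#' where `a0` is `a0t` (or `a0t/clk` when `clk_mode = "divide_a0t"`). The curve
#' is strictly positive and unimodal in `v`.
#'
#' @inheritParams bg_steady_state
#' @return Time constant (ms).
#' @export
bg_time_constant <- function(v, p) {
  stopifnot(inherits(p, "bg_params"))
  v <- .bg_check_v(v)
  a0 <- if (p$clk_mode == "multiply_a0t") p$a0t * p$clk else p$a0t
  num <- exp(p$kT * p$zeta_t * p$gmt * (v - p$vhalf_t))
  den <- p$temperature_factor * a0 * (1 + exp(p$kT * p$zeta_t * (v - p$vhalf_t)))
  num / den
}

## ---- gate / channel specification -----------------------------------------

.GATE_FORMS <- c("borg_graham", "alpha_beta", "inf_tau", "calcium_hill")

.GATE_REQUIRED <- list(
  borg_graham = c("vhalf_l", "vhalf_t", "a0t", "zeta_l", "zeta_t", "gmt"),
  alpha_beta = c("a_form", "a_rate", "a_vhalf", "a_slope",
                 "b_form", "b_rate", "b_vhalf", "b_slope"),
  inf_tau = c("vhalf", "slope", "tau_min", "tau_amp", "tau_vhalf", "tau_slope"),
  calcium_hill = c("n", "khalf_mM", "tau_ms")
)

#' Specify one gating variable
#'
#' @param name Gate label (e.g. `"m"`, `"h"`, `"n"`).
#' @param power Non-negative integer exponent in the conductance product.
#' @param form One of `"borg_graham"`, `"alpha_beta"`, `"inf_tau"`,
#'   `"calcium_hill"`.
#' @param parameters Named numeric list; required names depend on the form.
#' @return A `gate_spec` object.
#' @export
gate_spec <- function(name, power, form, parameters) {
  form <- match.arg(form, .GATE_FORMS)
  if (!is.numeric(power) || power < 0 || power != round(power))
    stop("gate power must be a non-negative integer")
  parameters <- as.list(parameters)
  req <- .GATE_REQUIRED[[form]]
  missing <- setdiff(req, names(parameters))
  if (length(missing))
    stop(sprintf("gate '%s' (%s): missing parameter(s) %s",
                 name, form, paste(missing, collapse = ", ")))
  structure(list(name = name, power = as.integer(power), form = form,
                 parameters = parameters),
            class = "gate_spec")
}

.CHANNEL_NAMES <- c("Nax", "Na3", "KDR", "KAp", "KAd", "KM", "KD",
                    "CaN", "CaL", "CaT", "KCa", "Cagk", "Ih")

#' Specify one membrane conductance
#'
#' @param name Channel label; the shipped library covers the CA1 set
#'   Nax, Na3, KDR, KAp, KAd, KM, KD, CaN, CaL, CaT, KCa, Cagk, Ih.
#' @param gates List of [gate_spec()] objects (possibly empty for a pure
#'   ohmic conductance).
#' @param reversal Reversal potential (mV).
#' @param calcium_flux_fraction Fraction of the channel current credited to
#'   the calcium pool, in \[0, 1\].
#' @return A `channel_spec` object.
#' @export
channel_spec <- function(name, gates, reversal, calcium_flux_fraction = 0) {
  if (!is.character(name) || length(name) != 1L) stop("name must be a string")
  gates <- lapply(gates, function(g) {
    if (!inherits(g, "gate_spec")) stop("gates must be gate_spec objects")
    g
  })
  if (!is.numeric(reversal) || !is.finite(reversal))
    stop("reversal must be a finite voltage (mV)")
  if (calcium_flux_fraction < 0 || calcium_flux_fraction > 1)
    stop("calcium_flux_fraction must lie in [0,1]")
  structure(list(name = name, gates = gates, reversal = reversal,
                 calcium_flux_fraction = calcium_flux_fraction),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("channel %s: %d gate(s), E = %g mV%s\n", x$name,
              length(x$gates), x$reversal,
              if (x$calcium_flux_fraction > 0)
                sprintf(", ca flux %.2f", x$calcium_flux_fraction) else ""))
  for (g in x$gates)
    cat(sprintf("  gate %s^%d (%s)\n", g$name, g$power, g$form))
  invisible(x)
}

#' Calcium pool parameters
#'
#' Submembrane calcium with single-exponential extrusion (default decay
#' 100 ms) driven by the calcium current density.
#'
#' @param decay_tau Extrusion time constant (ms); default 100.
#' @param resting_concentration Resting calcium (mM); default 50 nM.
#' @param current_to_concentration_gain mM per (mA/cm2 * ms); default 0.01,
#'   corresponding to a ~0.5 um submembrane shell.
#' @return A `calcium_pool` object.
#' @export
calcium_pool <- function(decay_tau = 100, resting_concentration = 5e-5,
                         current_to_concentration_gain = 0.01) {
  if (decay_tau <= 0) stop("decay_tau must be > 0")
  if (resting_concentration < 0) stop("resting concentration must be >= 0")
  structure(list(decay_tau = decay_tau,
                 resting_concentration = resting_concentration,
                 current_to_concentration_gain = current_to_concentration_gain),
            class = "calcium_pool")
}

## Species presets for the fitted h-current --------------------------------

.IH_PRESETS <- list(
  mouse = list(vhalf_l = -77.46, vhalf_t = -70.24, a0t = 4.7e-3,
               zeta_l = 3.5, zeta_t = 7.3, gmt = 0.145, clk = 0.24),
  rat   = list(vhalf_l = -69.5, vhalf_t = -64.1, a0t = 7.2e-3,
               zeta_l = 5.2, zeta_t = 15.8, gmt = 0.067, clk = 1)
)

#' Species-specific h-current parameters
#'
#' Returns the fitted Borg-Graham parameters of the hyperpolarization-
#' activated h-current (Ih) for the requested species.
#'
#' @param species `"mouse"` or `"rat"`.
#' @param clk_mode Passed to [bg_params()].
#' @return A [bg_params()] object.
#' @export
ih_params <- function(species = c("mouse", "rat"),
                      clk_mode = c("inert", "multiply_a0t")) {
  species <- match.arg(species)
  p <- .IH_PRESETS[[species]]
  bg_params(vhalf_l = p$vhalf_l, vhalf_t = p$vhalf_t, a0t = p$a0t,
            zeta_l = p$zeta_l, zeta_t = p$zeta_t, gmt = p$gmt, clk = p$clk,
            clk_mode = match.arg(clk_mode))
}

#' Build the h-current channel for one species
#'
#' @inheritParams ih_params
#' @param reversal Ih reversal potential (mV); default -30.
#' @return A [channel_spec()] with a single Borg-Graham gate of power 1.
#' @export
make_ih_preset <- function(species = c("mouse", "rat"), reversal = -30) {
  species <- match.arg(species)
  p <- .IH_PRESETS[[species]]
  g <- gate_spec("l", 1L, "borg_graham",
                 c(p, list(temperature_factor = 1, kT = .kT_DEFAULT)))
  channel_spec("Ih", list(g), reversal = reversal)
}

## Evaluation (reference R path; the simulator has its own compiled path) ----

.gate_inf_tau <- function(gate, v, ca = 0) {
  p <- gate$parameters
  switch(gate$form,
    borg_graham = {
      bp <- bg_params(p$vhalf_l, p$vhalf_t, p$a0t, p$zeta_l, p$zeta_t, p$gmt,
                      clk = if (is.null(p$clk)) 1 else p$clk,
                      temperature_factor =
                        if (is.null(p$temperature_factor)) 1
                        else p$temperature_factor,
                      kT = if (is.null(p$kT)) .kT_DEFAULT else p$kT)
      list(inf = bg_steady_state(v, bp), tau = bg_time_constant(v, bp))
    },
    alpha_beta = {
      rate <- function(form, a, vh, k, v) {
        ## form 1 exponential, 2 sigmoid, 3 linoid (with removable singularity)
        if (form == 1) a * exp((v - vh) / k)
        else if (form == 2) a / (1 + exp(-(v - vh) / k))
        else {
          x <- (v - vh) / k
          ifelse(abs(x) < 1e-6, a * k * (1 - x / 2), a * (v - vh) / (1 - exp(-x)))
        }
      }
      al <- rate(p$a_form, p$a_rate, p$a_vhalf, p$a_slope, v)
      be <- rate(p$b_form, p$b_rate, p$b_vhalf, p$b_slope, v)
      taumin <- if (is.null(p$tau_min)) 0 else p$tau_min
      list(inf = al / (al + be), tau = pmax(1 / (al + be), taumin))
    },
    inf_tau = {
      inf <- 1 / (1 + exp((v - p$vhalf) / p$slope))
      tau <- p$tau_min + p$tau_amp /
        (exp((v - p$tau_vhalf) / p$tau_slope) +
         exp(-(v - p$tau_vhalf) / p$tau_slope))
      list(inf = inf, tau = tau)
    },
    calcium_hill = {
      kh <- p$khalf_mM
      if (!is.null(p$vslope) && p$vslope != 0) {
        vref <- if (is.null(p$vref)) -20 else p$vref
        kh <- kh * exp(-(v - vref) / p$vslope)
      }
      can <- pmax(ca, 0)^p$n
      list(inf = can / (can + kh^p$n), tau = rep_len(p$tau_ms, length(v)))
    })
}

#' Instantaneous channel current and gate derivatives
#'
#' Ohmic evaluation `gbar * prod(gate^power) * (v - E)` with first-order gate
#' relaxation `dx/dt = (xinf - x)/tau`. This reference path mirrors the
#' compiled simulator and backs the package's unit tests.
#'
#' @param state Named list with `gates` (numeric vector, one entry per gate,
#'   each in \[0,1\]), `v` (mV) and optionally `ca` (mM).
#' @param spec A [channel_spec()].
#' @param gbar Peak conductance density (S/cm2), non-negative.
#' @return List with `current` (mA/cm2), `ca_current` (mA/cm2 credited to the
#'   calcium pool) and `dgates` (1/ms).
#' @export
evaluate_channel <- function(state, spec, gbar) {
  stopifnot(inherits(spec, "channel_spec"), gbar >= 0)
  g <- state$gates
  if (length(g) != length(spec$gates))
    stop("state has wrong number of gate values")
  if (length(g) && (any(g < 0) || any(g > 1)))
    stop("gate values must lie in [0,1]")
  ca <- if (is.null(state$ca)) 0 else state$ca
  open <- 1
  dg <- numeric(length(g))
  for (i in seq_along(spec$gates)) {
    gs <- spec$gates[[i]]
    open <- open * g[i]^gs$power
    it <- .gate_inf_tau(gs, state$v, ca)
    dg[i] <- (it$inf - g[i]) / it$tau
  }
  cur <- gbar * open * (state$v - spec$reversal)
  list(current = cur, ca_current = cur * spec$calcium_flux_fraction,
       dgates = dg)
}

## ---- channel definition files ---------------------------------------------

.channel_to_list <- function(spec) {
  list(name = spec$name,
       reversal = spec$reversal,
       calcium_flux_fraction = spec$calcium_flux_fraction,
       gates = lapply(spec$gates, function(g)
         list(name = g$name, power = g$power, form = g$form,
              parameters = g$parameters)))
}

.channel_from_list <- function(x) {
  gates <- lapply(x$gates, function(g) {
    if (is.null(g$form) || !g$form %in% .GATE_FORMS)
      stop(sprintf("unknown gate form '%s'", as.character(g$form)))
    gate_spec(g$name, g$power, g$form, g$parameters)
  })
  cff <- if (is.null(x$calcium_flux_fraction)) 0 else x$calcium_flux_fraction
  channel_spec(x$name, gates, x$reversal, cff)
}

#' Load a channel-definition library from JSON
#'
#' @param path Path to a JSON channel library (an array of channel objects).
#' @return Named list of [channel_spec()] objects.
#' @export
load_channel_definitions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(raw, .channel_from_list)
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate channel name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  stats::setNames(specs, nm)
}

#' Write a channel library to JSON
#'
#' @param specs Named list of [channel_spec()] objects.
#' @param path Output path.
#' @export
write_channel_definitions <- function(specs, path) {
  jsonlite::write_json(lapply(unname(specs), .channel_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Shipped default channel library for one species
#'
#' Loads the package's CA1 channel family (13 channels) with the
#' species-specific h-current preset substituted in.
#'
#' @inheritParams ih_params
#' @return Named list of [channel_spec()] objects.
#' @export
default_channel_library <- function(species = c("mouse", "rat")) {
  species <- match.arg(species)
  path <- system.file("extdata", "channels",
                      paste0("default_", species, ".json"),
                      package = "ca1pyr", mustWork = TRUE)
  load_channel_definitions(path)
}
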