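## Current-clamp protocol suites and synaptic spike-train generators.

#' Current-clamp protocol suite
#'
#' Two suites mirror the in vitro protocols: a depolarizing suite of 6
#' positive amplitudes and a hyperpolarizing suite of 4 negative amplitudes.
#'
#' @param name `"APwaveform"` (positive) or `"HyperDePol"` (negative).
#' @param amplitudes Override amplitudes (nA); signs must match the suite.
#' @param delay Stimulus onset (ms).
#' @param duration Stimulus duration (ms).
#' @return A `protocol_suite` object.
#' @export
make_protocol_suite <- function(name = c("APwaveform", "HyperDePol"),
                                amplitudes = NULL, delay = 100,
                                duration = 400) {
  name <- match.arg(name)
  if (is.null(amplitudes))
    amplitudes <- if (name == "APwaveform")
      seq(0.15, 0.65, by = 0.1) else seq(-0.05, -0.2, by = -0.05)
  if (name == "APwaveform" && any(amplitudes <= 0))
    stop("APwaveform amplitudes must all be positive")
  if (name == "HyperDePol" && any(amplitudes >= 0))
    stop("HyperDePol amplitudes must all be negative")
  structure(list(name = name, amplitudes = amplitudes, delay = delay,
                 duration = duration),
            class = "protocol_suite")
}

#' @export
print.protocol_suite <- function(x, ...) {
  cat(sprintf("protocol_suite %s: %d amplitudes (%s nA), %g ms at %g ms\n",
              x$name, length(x$amplitudes),
              paste(x$amplitudes, collapse = ", "), x$duration, x$delay))
  invisible(x)
}

#' Homogeneous Poisson spike trains
#'
#' @param rate Rate (Hz), > 0.
#' @param duration Duration (ms), > 0.
#' @param n Number of trains.
#' @param seed Integer seed.
#' @param synchronous If TRUE, one train is drawn and replicated `n` times;
#'   otherwise `n` independent trains.
#' @return List of `n` numeric vectors of spike times (ms).
#' @export
poisson_trains <- function(rate, duration, n, seed = 1, synchronous = FALSE) {
  if (rate <= 0 || duration <= 0) stop("rate and duration must be > 0")
  draw <- function() {
    ## exponential inter-arrival sampling; mean ISI in ms
    mean_isi <- 1000 / rate
    t <- cumsum(rexp(ceiling(duration / mean_isi * 3) + 20, 1 / mean_isi))
    while (length(t) && t[length(t)] < duration)
      t <- c(t, t[length(t)] +
               cumsum(rexp(20, 1 / mean_isi)))
    t[t < duration]
  }
  with_local_seed(seed, {
    if (synchronous) {
      tr <- draw()
      replicate(n, tr, simplify = FALSE)
    } else replicate(n, draw(), simplify = FALSE)
  })
}

#' Theta-paced bursts of gamma spikes
#'
#' Burst onsets follow a homogeneous Poisson process at `theta_rate`; each
#' burst carries `spikes_per_burst` spikes at regular `1/gamma_rate`
#' intervals. Expected total rate is `theta_rate * spikes_per_burst`.
#'
#' @param theta_rate Burst-onset rate (Hz).
#' @param gamma_rate Within-burst spike rate (Hz), > `theta_rate`.
#' @param spikes_per_burst Spikes per burst (>= 1).
#' @param duration Duration (ms).
#' @param n Number of trains.
#' @param seed Integer seed.
#' @param synchronous Replicate one train if TRUE.
#' @return List of `n` numeric vectors of spike times (ms).
#' @export
theta_gamma_burst_trains <- function(theta_rate, gamma_rate,
                                     spikes_per_burst = 5, duration, n,
                                     seed = 1, synchronous = FALSE) {
  if (gamma_rate <= theta_rate) stop("need gamma_rate > theta_rate")
  if (spikes_per_burst < 1) stop("spikes_per_burst must be >= 1")
  onsets <- poisson_trains(theta_rate, duration, n, seed,
                           synchronous = synchronous)
  gap <- 1000 / gamma_rate
  lapply(onsets, function(on) {
    t <- as.numeric(outer(on, (seq_len(spikes_per_burst) - 1) * gap, "+"))
    sort(t[t < duration])
  })
}

#' Synaptic stimulation regime
#'
#' A stimulation condition for the in vivo-like experiments: average input
#' rate in the theta (8, 10 Hz) or gamma (40, 60, 80 Hz) range, synchronous
#' or asynchronous activation, number of synapses and a synaptic weight
#' scale.
#'
#' @param rate Average activation rate (Hz).
#' @param mode `"synchronous"`, `"asynchronous"` or `"theta_gamma_burst"`.
#' @param n_synapses Number of synapses (default 80).
#' @param weight_scale Multiplier on the 0.25 nS base weight (default 1).
#' @param duration Stimulation duration (ms).
#' @param seed Integer seed.
#' @param theta_rate,spikes_per_burst Burst-mode parameters (`rate` is the
#'   within-burst gamma rate).
#' @return A `synaptic_regime` object.
#' @export
synaptic_regime <- function(rate, mode = c("asynchronous", "synchronous",
                                           "theta_gamma_burst"),
                            n_synapses = 80, weight_scale = 1,
                            duration = 2000, seed = 1, theta_rate = 8,
                            spikes_per_burst = 5) {
  mode <- match.arg(mode)
  if (rate <= 0 || n_synapses < 1 || weight_scale <= 0)
    stop("invalid regime parameters")
  structure(list(rate = rate, mode = mode, n_synapses = n_synapses,
                 weight_scale = weight_scale, duration = duration,
                 seed = seed, theta_rate = theta_rate,
                 spikes_per_burst = spikes_per_burst),
            class = "synaptic_regime")
}

#' Spike trains for a regime
#' @param regime A [synaptic_regime()].
#' @return List of spike-time vectors, one per synapse.
#' @export
regime_trains <- function(regime) {
  switch(regime$mode,
    asynchronous = poisson_trains(regime$rate, regime$duration,
                                  regime$n_synapses, regime$seed),
    synchronous = poisson_trains(regime$rate, regime$duration,
                                 regime$n_synapses, regime$seed,
                                 synchronous = TRUE),
    theta_gamma_burst = theta_gamma_burst_trains(
      regime$theta_rate, regime$rate, regime$spikes_per_burst,
      regime$duration, regime$n_synapses, regime$seed))
}
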