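## In vivo-like experiments: theta/gamma synaptic drive, inverse-ISI
## distributions, the sharp-wave-ripple (150-250 Hz) band, and the
## synaptic weight-scaling experiment.

.BASE_SYNAPTIC_WEIGHT_nS <- 0.25

#' Drive a cell with a synaptic regime
#'
#' Places `n_synapses` AMPA synapses by the species placement rule, attaches
#' the regime's spike trains at weight `0.25 nS x weight_scale`, simulates,
#' and detects output spikes at the -20 mV convention. Reproducible
#' end-to-end from the regime seed.
#'
#' @param cell A `cable_cell` (species preset recommended).
#' @param regime A [synaptic_regime()].
#' @param rule Placement rule; defaults to the preset of the cell's species
#'   attribute (falling back to mouse).
#' @param dt Time step (ms).
#' @param settle_ms Settling time (ms).
#' @return List: `trace` ([voltage_trace()]), `spike_times` (ms), `sites`,
#'   `regime`.
#' @export
run_regime <- function(cell, regime, rule = NULL, dt = 0.025,
                       settle_ms = 500) {
  if (is.null(rule)) {
    sp <- attr(cell, "species")
    rule <- synapse_rule_preset(if (is.null(sp)) "mouse" else sp)
  }
  sites <- eligible_synapse_sites(cell$comps, rule, regime$n_synapses,
                                  seed = regime$seed)
  trains <- regime_trains(regime)
  w <- .BASE_SYNAPTIC_WEIGHT_nS * regime$weight_scale
  for (k in seq_len(regime$n_synapses))
    cell <- attach_double_exp_synapse(cell, sites$comp[k], weight = w,
                                      spike_times = trains[[k]])
  tr <- simulate(cell, sim_config(t_stop = regime$duration, dt = dt,
                                  settle_ms = settle_ms),
                 meta = list(protocol = paste0("synaptic_", regime$mode),
                             rate_Hz = regime$rate,
                             weight_scale = regime$weight_scale,
                             delay_ms = 0, duration_ms = regime$duration))
  list(trace = tr, spike_times = detect_spikes(tr), sites = sites,
       regime = regime)
}

#' Inverse inter-spike-interval distribution
#'
#' Instantaneous firing frequencies `1000 / ISI` (Hz) with a histogram over
#' configurable bins (default 0-300 Hz in 10 Hz steps; values beyond the
#' last edge are collected in the final count so counts always sum to the
#' number of ISIs).
#'
#' @param spike_times Spike times (ms).
#' @param breaks Histogram bin edges (Hz).
#' @return An `isi_distribution`: list with `values` (Hz), `breaks`,
#'   `counts`, `n_spikes`.
#' @export
isi_inverse_distribution <- function(spike_times,
                                     breaks = seq(0, 300, by = 10)) {
  spike_times <- sort(spike_times)
  values <- if (length(spike_times) >= 2) 1000 / diff(spike_times)
            else numeric(0)
  edges <- c(breaks, Inf)
  counts <- if (length(values))
    as.integer(table(cut(values, edges, right = FALSE)))
  else integer(length(edges) - 1)
  structure(list(values = values, breaks = breaks, counts = counts,
                 n_spikes = length(spike_times)),
            class = "isi_distribution")
}

#' @export
print.isi_distribution <- function(x, ...) {
  cat(sprintf("isi_distribution: %d spikes, %d ISIs, median %.1f Hz\n",
              x$n_spikes, length(x$values),
              if (length(x$values)) median(x$values) else NA))
  invisible(x)
}

#' Fraction of instantaneous frequencies in a band
#'
#' @param dist An `isi_distribution`.
#' @param band Closed frequency band (Hz); default the sharp-wave-ripple
#'   range 150-250 Hz.
#' @return Fraction in \[0, 1\], or NA for an empty distribution.
#' @export
swr_band_fraction <- function(dist, band = c(150, 250)) {
  if (!length(dist$values)) return(NA_real_)
  mean(dist$values >= band[1] & dist$values <= band[2])
}

#' Group spikes into bursts
#'
#' Consecutive ISIs below `max_isi_ms` (default 10 ms) are grouped into one
#' burst; used descriptively for reporting burst occurrence.
#'
#' @param spike_times Spike times (ms).
#' @param max_isi_ms Intra-burst ISI bound (ms).
#' @return Integer burst id per spike.
#' @export
burst_labels <- function(spike_times, max_isi_ms = 10) {
  if (!length(spike_times)) return(integer(0))
  cumsum(c(1L, as.integer(diff(sort(spike_times)) >= max_isi_ms)))
}

#' Synaptic weight-scaling experiment
#'
#' Runs the same regime (identical seed, hence identical synapse placement
#' and spike trains) at several weight scale factors and reports the
#' SWR-band fraction per factor plus the qualitative flag
#' `high_frequency_component` (band fraction > 0 with at least 3 events).
#'
#' @param cell A `cable_cell`.
#' @param base_regime A [synaptic_regime()] (the scale factor inside it is
#'   ignored).
#' @param factors Weight scale factors; default `c(1, 3)`.
#' @param band Frequency band (Hz).
#' @param ... Passed to [run_regime()].
#' @return Data frame (factor, n_spikes, swr_fraction,
#'   high_frequency_component) with the per-factor distributions in the
#'   `"distributions"` attribute.
#' @export
weight_scaling_experiment <- function(cell, base_regime, factors = c(1, 3),
                                      band = c(150, 250), ...) {
  if (any(factors <= 0)) stop("scale factors must be > 0")
  dists <- list()
  rows <- lapply(factors, function(f) {
    rg <- base_regime
    rg$weight_scale <- f
    res <- run_regime(cell, rg, ...)
    d <- isi_inverse_distribution(res$spike_times)
    dists[[as.character(f)]] <<- d
    frac <- swr_band_fraction(d, band)
    n_in_band <- if (length(d$values))
      sum(d$values >= band[1] & d$values <= band[2]) else 0L
    data.frame(factor = f, n_spikes = d$n_spikes,
               swr_fraction = ifelse(is.na(frac), 0, frac),
               high_frequency_component = !is.na(frac) && frac > 0 &&
                 n_in_band >= 3)
  })
  out <- do.call(rbind, rows)
  attr(out, "distributions") <- dists
  out
}
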