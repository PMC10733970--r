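## Electrophysiological feature extraction from voltage traces.
##
## Conventions: the AP detection threshold is -20 mV (one spike per
## contiguous suprathreshold window, timed at the window's voltage peak);
## AP width is measured at that threshold; spike-dependent features are
## absent (NA), never zero, when no spike qualifies. Units: mV, ms, Hz,
## MOhm; adaptation index dimensionless.

#' Detect spikes in a voltage trace
#'
#' One spike per contiguous window above `threshold`, timed at the voltage
#' peak within the window.
#'
#' @param trace A [voltage_trace()].
#' @param threshold Detection threshold (mV); default -20.
#' @return Numeric vector of spike times (ms), possibly empty.
#' @export
detect_spikes <- function(trace, threshold = -20) {
  v <- trace$v_mV
  t <- trace$t_ms
  above <- v > threshold
  if (!any(above)) return(numeric(0))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  vapply(seq_along(starts), function(k) {
    w <- starts[k]:ends[k]
    t[w[which.max(v[w])]]
  }, numeric(1))
}

#' Spike-timing features
#'
#' Counts restricted to the stimulus interval; times relative to stimulus
#' onset; `inv_k_ISI` in Hz (`1000/ISI_k`); `mean_frequency` =
#' count / stimulus duration.
#'
#' @param spike_times Spike times (ms).
#' @param onset Stimulus onset (ms).
#' @param duration Stimulus duration (ms).
#' @return Named list: spikecount_stimint, mean_frequency,
#'   time_to_first_spike, time_to_last_spike, inv_first_ISI ...
#'   inv_fifth_ISI, inv_last_ISI. Undefined entries are NA.
#' @export
timing_features <- function(spike_times, onset, duration) {
  if (duration <= 0) stop("invalid stimulus window")
  st <- spike_times[spike_times >= onset & spike_times <= onset + duration]
  n <- length(st)
  out <- list(spikecount_stimint = n,
              mean_frequency = n / (duration / 1000),
              time_to_first_spike = if (n) st[1] - onset else NA_real_,
              time_to_last_spike = if (n) st[n] - onset else NA_real_)
  isi <- diff(st)
  ord <- c("first", "second", "third", "fourth", "fifth")
  for (k in 1:5)
    out[[paste0("inv_", ord[k], "_ISI")]] <-
      if (length(isi) >= k) 1000 / isi[k] else NA_real_
  out$inv_last_ISI <- if (length(isi)) 1000 / isi[length(isi)] else NA_real_
  out
}

#' Spike-frequency adaptation index
#'
#' Mean over consecutive ISI pairs of
#' `(ISI[i+1] - ISI[i]) / (ISI[i+1] + ISI[i])`; positive under adaptation.
#'
#' @param spike_times Spike times (ms); needs >= 3 spikes.
#' @return Dimensionless index, or NA with fewer than 3 spikes.
#' @export
adaptation_index <- function(spike_times) {
  if (length(spike_times) < 3) return(NA_real_)
  isi <- diff(spike_times)
  mean((isi[-1] - isi[-length(isi)]) / (isi[-1] + isi[-length(isi)]))
}

.cross_time <- function(t, v, i, threshold) {
  ## linear interpolation of the crossing between samples i and i+1
  t[i] + (threshold - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' Action-potential shape features
#'
#' For the first detected spike: amplitude above the detection threshold,
#' width at the threshold (between the upward and downward crossings around
#' the peak, linearly interpolated), and the phase plot (v, dv/dt by central
#' differences) over the whole trace.
#'
#' @param trace A [voltage_trace()].
#' @param spike_times From [detect_spikes()]; defaults to detecting here.
#' @param threshold Detection threshold (mV).
#' @return Named list: AP_amplitude (mV), AP_width (ms), phase_plot
#'   (data.frame v, dvdt). AP features are NA if the spike is truncated at
#'   a trace edge.
#' @export
shape_features <- function(trace, spike_times = NULL, threshold = -20) {
  if (is.null(spike_times)) spike_times <- detect_spikes(trace, threshold)
  t <- trace$t_ms
  v <- trace$v_mV
  dt <- t[2] - t[1]
  dvdt <- c(NA, (v[-(1:2)] - v[1:(length(v) - 2)]) / (2 * dt), NA)
  phase <- data.frame(v = v, dvdt = dvdt)
  if (!length(spike_times))
    return(list(AP_amplitude = NA_real_, AP_width = NA_real_,
                phase_plot = phase))
  ip <- which.min(abs(t - spike_times[1]))
  up <- ip
  while (up > 1 && v[up - 1] > threshold) up <- up - 1
  dn <- ip
  while (dn < length(v) && v[dn + 1] > threshold) dn <- dn + 1
  if (up == 1 || dn == length(v))
    return(list(AP_amplitude = NA_real_, AP_width = NA_real_,
                phase_plot = phase))
  t_up <- .cross_time(t, v, up - 1, threshold)
  t_dn <- .cross_time(t, v, dn, threshold)
  list(AP_amplitude = v[ip] - threshold, AP_width = t_dn - t_up,
       phase_plot = phase)
}

#' Subthreshold voltage features
#'
#' `voltage_base` is the mean pre-stimulus voltage; `steady_state_voltage`
#' the mean over the final 10% of the stimulus; `voltage_deflection` their
#' difference; `sag_amplitude` the rebound from the stimulus minimum to the
#' steady state (>= 0).
#'
#' @param trace A [voltage_trace()].
#' @param onset Stimulus onset (ms).
#' @param duration Stimulus duration (ms).
#' @return Named list of the four features (mV).
#' @export
subthreshold_features <- function(trace, onset, duration) {
  t <- trace$t_ms
  if (onset < t[1] || onset + duration > t[length(t)] + 1e-9)
    stop("stimulus window outside trace")
  v <- trace$v_mV
  base <- mean(v[t < onset])
  ss_win <- t >= onset + 0.9 * duration & t <= onset + duration
  ss <- mean(v[ss_win])
  vmin <- min(v[t >= onset & t <= onset + duration])
  list(voltage_base = base, steady_state_voltage = ss,
       voltage_deflection = ss - base,
       sag_amplitude = max(ss - vmin, 0))
}

#' Membrane time constant
#'
#' Single-exponential least-squares fit to the initial voltage relaxation
#' during a hyperpolarizing step. The fit window runs from onset to the time
#' of the voltage minimum, capped at 100 ms, avoiding sag contamination.
#'
#' @param trace A [voltage_trace()] of a hyperpolarizing response.
#' @param onset Stimulus onset (ms).
#' @param duration Stimulus duration (ms).
#' @param cap_ms Fit-window cap (ms); default 100.
#' @return Time constant (ms), or NA if the fit fails.
#' @export
membrane_time_constant <- function(trace, onset, duration, cap_ms = 100) {
  t <- trace$t_ms
  v <- trace$v_mV
  sub <- subthreshold_features(trace, onset, duration)
  if (sub$voltage_deflection >= 0)
    stop("membrane time constant requires a hyperpolarizing response")
  stim <- t >= onset & t <= onset + duration
  t_min <- t[stim][which.min(v[stim])]
  w <- t >= onset & t <= min(t_min, onset + cap_ms)
  tw <- t[w] - onset
  vw <- v[w]
  fit <- tryCatch({
    st <- list(a = vw[length(vw)], b = vw[1] - vw[length(vw)], tau = 15)
    ## warnOnly + own validity check below; convergence chatter suppressed
    suppressWarnings(
      stats::nls(vw ~ a + b * exp(-tw / tau), start = st,
                 control = stats::nls.control(warnOnly = TRUE,
                                              maxiter = 500,
                                              minFactor = 1e-10)))
  }, error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  tau <- coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) NA_real_ else tau
}

#' Input resistance from a trace set
#'
#' Ohm's law on the steady-state deflection of the smallest-magnitude
#' negative current injection.
#'
#' @param traces List of [voltage_trace()] objects with `amplitude_nA`,
#'   `delay_ms`, `duration_ms` metadata.
#' @return Input resistance (MOhm).
#' @export
input_resistance <- function(traces) {
  amps <- vapply(traces, function(tr) tr$meta$amplitude_nA, numeric(1))
  neg <- which(amps < 0)
  if (!length(neg)) stop("no negative current injection available")
  k <- neg[which.min(abs(amps[neg]))]
  tr <- traces[[k]]
  sub <- subthreshold_features(tr, tr$meta$delay_ms, tr$meta$duration_ms)
  sub$voltage_deflection / amps[k]
}

#' Full feature set of one trace
#'
#' Extracts the optimization feature panel (subthreshold + spike-timing
#' features) and the AP shape features from one trace.
#'
#' @param trace A [voltage_trace()] with stimulus metadata.
#' @param threshold Spike detection threshold (mV).
#' @return Named list of feature values (NA = absent).
#' @export
extract_features <- function(trace, threshold = -20) {
  meta <- trace$meta
  if (is.null(meta$delay_ms) || is.null(meta$duration_ms))
    stop("trace metadata must carry delay_ms and duration_ms")
  st <- detect_spikes(trace, threshold)
  out <- c(subthreshold_features(trace, meta$delay_ms, meta$duration_ms),
           timing_features(st, meta$delay_ms, meta$duration_ms))
  out$adaptation_index <- adaptation_index(
    st[st >= meta$delay_ms & st <= meta$delay_ms + meta$duration_ms])
  sh <- shape_features(trace, st, threshold)
  out$AP_amplitude <- sh$AP_amplitude
  out$AP_width <- sh$AP_width
  out
}

## ---- trend and group statistics -------------------------------------------

#' Per-species trends and per-amplitude group comparison
#'
#' For each species, the ordinary-least-squares slope of the mean feature
#' value versus injected current; for each amplitude present in both
#' species, a two-sample comparison (Student t when both groups pass a
#' Shapiro normality check at alpha 0.05, Mann-Whitney rank-sum otherwise).
#' No multiple-testing correction is applied.
#'
#' @param df Data frame with columns `cell`, `species`, `amplitude`,
#'   `value`.
#' @return List with `slopes` (named by species, units value/nA) and
#'   `comparisons` (data.frame amplitude, test, p_value).
#' @export
trend_and_group_stats <- function(df) {
  stopifnot(all(c("cell", "species", "amplitude", "value") %in% names(df)))
  df <- df[is.finite(df$value), , drop = FALSE]
  slopes <- sapply(split(df, df$species), function(d) {
    means <- tapply(d$value, d$amplitude, mean)
    if (length(means) < 2) return(NA_real_)
    amp <- as.numeric(names(means))
    unname(coef(lm(means ~ amp))[2])
  })
  amps <- sort(unique(df$amplitude))
  comps <- lapply(amps, function(a) {
    d <- df[df$amplitude == a, ]
    gr <- split(d$value, d$species)
    if (length(gr) < 2 || any(lengths(gr) < 2))
      return(data.frame(amplitude = a, test = NA, p_value = NA_real_))
    normal <- all(vapply(gr, function(x) {
      if (length(x) < 3 || length(unique(x)) < 3) return(FALSE)
      shapiro.test(x)$p.value > 0.05
    }, logical(1)))
    if (normal) {
      pt <- t.test(gr[[1]], gr[[2]])$p.value
      data.frame(amplitude = a, test = "t", p_value = pt)
    } else {
      pw <- suppressWarnings(wilcox.test(gr[[1]], gr[[2]])$p.value)
      data.frame(amplitude = a, test = "rank-sum", p_value = pw)
    }
  })
  list(slopes = slopes, comparisons = do.call(rbind, comps))
}
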