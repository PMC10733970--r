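# Independent brute-force oracles, deliberately written with naive loops and
# kept separate from the package code paths. The reference feature library
# the definitions come from is not available in this environment, so these
# serve as the independent cross-check implementation.

oracle_detect_spikes <- function(t, v, threshold = -20) {
  times <- numeric(0)
  i <- 1
  n <- length(v)
  while (i <= n) {
    if (v[i] > threshold) {
      j <- i
      while (j < n && v[j + 1] > threshold) j <- j + 1
      best <- i
      for (k in i:j) if (v[k] > v[best]) best <- k
      times <- c(times, t[best])
      i <- j + 1
    } else i <- i + 1
  }
  times
}

oracle_timing <- function(spikes, onset, duration) {
  st <- c()
  for (s in spikes) if (s >= onset && s <= onset + duration) st <- c(st, s)
  isi <- c()
  if (length(st) > 1)
    for (k in 2:length(st)) isi <- c(isi, st[k] - st[k - 1])
  res <- list(spikecount_stimint = length(st),
              mean_frequency = length(st) / (duration / 1000),
              time_to_first_spike = if (length(st)) st[1] - onset else NA,
              time_to_last_spike = if (length(st)) st[length(st)] - onset
                                   else NA)
  labels <- c("inv_first_ISI", "inv_second_ISI", "inv_third_ISI",
              "inv_fourth_ISI", "inv_fifth_ISI")
  for (k in 1:5)
    res[[labels[k]]] <- if (length(isi) >= k) 1000 / isi[k] else NA
  res$inv_last_ISI <- if (length(isi)) 1000 / isi[length(isi)] else NA
  res
}

oracle_adaptation <- function(spikes) {
  if (length(spikes) < 3) return(NA)
  isi <- diff(spikes)
  acc <- 0
  for (k in 1:(length(isi) - 1))
    acc <- acc + (isi[k + 1] - isi[k]) / (isi[k + 1] + isi[k])
  acc / (length(isi) - 1)
}

oracle_subthreshold <- function(t, v, onset, duration) {
  base <- mean(v[t < onset])
  ss <- mean(v[t >= onset + 0.9 * duration & t <= onset + duration])
  vmin <- Inf
  for (k in seq_along(t))
    if (t[k] >= onset && t[k] <= onset + duration && v[k] < vmin) vmin <- v[k]
  list(voltage_base = base, steady_state_voltage = ss,
       voltage_deflection = ss - base,
       sag_amplitude = max(ss - vmin, 0))
}

oracle_ap_width <- function(t, v, threshold = -20) {
  spikes <- oracle_detect_spikes(t, v, threshold)
  if (!length(spikes)) return(list(AP_amplitude = NA, AP_width = NA))
  ip <- which(t == spikes[1])[1]
  up <- ip
  while (up > 1 && v[up - 1] > threshold) up <- up - 1
  dn <- ip
  while (dn < length(v) && v[dn + 1] > threshold) dn <- dn + 1
  if (up == 1 || dn == length(v)) return(list(AP_amplitude = NA,
                                              AP_width = NA))
  lerp <- function(i) t[i] + (threshold - v[i]) / (v[i + 1] - v[i]) *
    (t[i + 1] - t[i])
  # upward crossing sits between up-1 and up; downward between dn and dn+1
  list(AP_amplitude = v[ip] - threshold,
       AP_width = lerp(dn) - lerp(up - 1))
}

# brute-force PCA via eigendecomposition of the covariance matrix
oracle_pca <- function(X, standardize = TRUE) {
  Xc <- scale(X, center = TRUE, scale = standardize)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  list(eigenvalues = ev$values, loadings = ev$vectors)
}

# panel of 20 synthetic traces covering subthreshold sags, regular and
# adapting trains, bursts, and edge cases; built analytically (no simulator)
oracle_trace_panel <- function() {
  dt <- 0.05
  t <- seq(0, 600, by = dt)
  spike_shape <- function(t0, amp = 80, width = 1.2)
    amp * exp(-((t - t0)^2) / (2 * (width / 2.355)^2))
  mk <- function(v) voltage_trace(t, v, meta = list(amplitude_nA = 0.3,
                                                    delay_ms = 100,
                                                    duration_ms = 400))
  panel <- list()
  set.seed(42)
  # 8 spiking traces with assorted regular/adapting/bursting patterns
  patterns <- list(
    seq(120, 480, by = 40), seq(120, 480, by = 25),
    120 + cumsum(c(0, 20 * 1.15^(0:10))), c(130, 144, 160, 178, 198, 220),
    c(125, 132, 139, 250, 257, 264, 380, 387),
    seq(150, 450, by = 75), c(140, 190), c(200))
  for (p in patterns) {
    v <- rep(-65, length(t))
    for (s in p[p < 560]) v <- v + spike_shape(s)
    v <- v + rnorm(length(t), 0, 0.05)
    panel[[length(panel) + 1]] <- mk(v)
  }
  # 8 subthreshold sag traces with varied kinetics
  for (k in 1:8) {
    tau1 <- 8 + 2 * k
    sag <- 2 + 0.5 * k
    depth <- -10 - k
    v <- rep(-65, length(t))
    stim <- t >= 100 & t <= 500
    ts <- t[stim] - 100
    v[stim] <- -65 + depth * (1 - exp(-ts / tau1)) +
      sag * (1 - exp(-ts / (tau1 * 6)))
    v[t > 500] <- -65 + (v[max(which(stim))] + 65) * exp(-(t[t > 500] - 500) / tau1)
    v <- v + rnorm(length(t), 0, 0.02)
    panel[[length(panel) + 1]] <- mk(v)
  }
  # 4 edge cases: flat, noisy flat, single wide spike, late spike
  v <- rep(-65, length(t)); panel[[length(panel) + 1]] <- mk(v)
  panel[[length(panel) + 1]] <- mk(v + rnorm(length(t), 0, 0.1))
  v <- rep(-65, length(t)) + spike_shape(300, width = 3)
  panel[[length(panel) + 1]] <- mk(v)
  v <- rep(-65, length(t)) + spike_shape(495)
  panel[[length(panel) + 1]] <- mk(v)
  panel
}
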