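## Two-stage model fitting.
##
## Stage 1 (prefit_ih): least-squares fit of the h-current kinetics plus
## passive membrane properties to hyperpolarizing voltage traces, reporting
## the RMS pointwise voltage error (target: below 0.3 mV).
##
## Stage 2 (run_evolution): feature-driven multi-objective evolutionary
## optimization of peak conductances. Objectives are per-feature z-scores
## |model - target| / sd; an individual with all z < 3 is acceptable.
## The GA is an elitist non-dominated-sorting algorithm with crowding over
## log10-scaled parameters.

#' Searchable parameter specification
#'
#' @param name Parameter name (`gbar_<channel>.<region>` or a passive name).
#' @param low,high Bounds (natural scale); `high/low` must be >= 10 (the
#'   search covers at least one order of magnitude) and `low > 0`
#'   (sampling is log-uniform).
#' @return A `parameter_spec` object.
#' @export
parameter_spec <- function(name, low, high) {
  if (low <= 0) stop("low bound must be > 0 (log-uniform sampling)")
  if (high / low < 10)
    stop("bounds must span at least one order of magnitude")
  structure(list(name = name, low = low, high = high),
            class = "parameter_spec")
}

#' Default conductance search space around a species preset
#'
#' Eight regional peak conductances searched over a factor of 10 around the
#' preset value (x/ 10^0.5 each way... bounds are preset/3.16 to preset*3.16,
#' i.e. one order of magnitude total span).
#'
#' @param species `"mouse"` or `"rat"`.
#' @param names Parameter subset; default the eight conductances that
#'   dominate excitability.
#' @return List of [parameter_spec()] objects.
#' @export
default_parameter_specs <- function(species = "mouse", names = NULL) {
  base <- .flatten_gbars(default_region_gbars(species))
  if (is.null(names))
    names <- c("gbar_Na3.soma", "gbar_Na3.apical_trunk", "gbar_Nax.axon",
               "gbar_KDR.soma", "gbar_KDR.axon", "gbar_KAp.soma",
               "gbar_KCa.soma", "gbar_KM.soma")
  lapply(names, function(nm)
    parameter_spec(nm, base[[nm]] / sqrt(10), base[[nm]] * sqrt(10)))
}

#' Build a cell from a parameter vector
#'
#' Species preset with the named regional conductances overridden. The
#' dendritic Na parameter (`gbar_Na3.apical_trunk`) is applied to all
#' dendritic regions.
#'
#' @param species `"mouse"` or `"rat"`.
#' @param params Named numeric vector of `gbar_<channel>.<region>` values.
#' @return A `cable_cell`.
#' @export
cell_from_params <- function(species, params) {
  gb <- default_region_gbars(species)
  if ("gbar_Na3.apical_trunk" %in% names(params)) {
    ## one dendritic Na parameter unless finer regional values are given
    v <- unname(params[["gbar_Na3.apical_trunk"]])
    if (!"gbar_Na3.oblique" %in% names(params)) gb$Na3$oblique <- v
    if (!"gbar_Na3.basal" %in% names(params)) gb$Na3$basal <- v
  }
  for (nm in names(params)) {
    parts <- strsplit(sub("^gbar_", "", nm), ".", fixed = TRUE)[[1]]
    gb[[parts[1]]][[parts[2]]] <- unname(params[[nm]])
  }
  cell_preset(species, region_gbars = gb)
}

#' Feature z-score objectives for one parameter vector
#'
#' Simulates every (protocol, amplitude) present in `targets`, extracts the
#' feature panel and scores `|feature - target| / sd` per target row. A
#' feature the model fails to produce where the target expects one (e.g. no
#' spikes) scores the documented penalty 250; a failed simulation scores the
#' penalty on every objective.
#'
#' @param params Named parameter vector.
#' @param targets Target table from [generate_target_features()].
#' @param species Species preset for the cell template.
#' @param dt Time step (ms); default 0.05 (twice the recording step: a
#'   deliberate forward-model economy, negligible against the target sds).
#' @param penalty Penalty z-score; default 250.
#' @return Numeric objective vector (one z per target row, all >= 0).
#' @export
evaluate_objectives <- function(params, targets, species = "mouse",
                                dt = 0.05, penalty = 250) {
  stopifnot(all(targets$sd > 0))
  z <- rep(penalty, nrow(targets))
  cell <- cell_from_params(species, params)
  combos <- unique(targets[c("protocol", "amplitude")])
  for (k in seq_len(nrow(combos))) {
    proto <- combos$protocol[k]
    amp <- combos$amplitude[k]
    suite <- make_protocol_suite(proto, amplitudes = amp)
    tr <- tryCatch({
      c2 <- inject_step_current(cell, "soma", amp, suite$delay,
                                suite$duration)
      simulate(c2, sim_config(t_stop = suite$delay + suite$duration + 100,
                              dt = dt, settle_ms = 500),
               meta = list(protocol = proto, amplitude_nA = amp,
                           delay_ms = suite$delay,
                           duration_ms = suite$duration))
    }, error = function(e) NULL)
    rows <- which(targets$protocol == proto & targets$amplitude == amp)
    if (is.null(tr)) next # keep penalty
    fx <- extract_features(tr)
    for (i in rows) {
      val <- fx[[targets$feature[i]]]
      if (!is.null(val) && is.finite(val))
        z[i] <- abs(val - targets$target[i]) / targets$sd[i]
    }
  }
  z
}

## ---- NSGA-II machinery -----------------------------------------------------

.nds_rank <- function(obj) {
  ## fast-enough nondominated sorting for desk-scale populations
  n <- nrow(obj)
  rank <- integer(n)
  dominated <- function(i, j) all(obj[j, ] <= obj[i, ]) &&
    any(obj[j, ] < obj[i, ])
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    front <- remaining[vapply(remaining, function(i)
      !any(vapply(remaining, function(j)
        j != i && dominated(i, j), logical(1))), logical(1))]
    rank[front] <- r
    remaining <- setdiff(remaining, front)
  }
  rank
}

.crowding <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  cd <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    cd[o[c(1, n)]] <- Inf
    if (rng > 0)
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] +
        (obj[o[3:n], m] - obj[o[1:(n - 2)], m]) / rng
  }
  cd
}

#' Multi-objective evolutionary optimization
#'
#' Elitist non-dominated-sorting GA with crowding over log10-scaled
#' parameters: log-uniform initialization, binary tournament selection,
#' SBX crossover and polynomial mutation. Deterministic given the seed.
#'
#' @param param_specs List of [parameter_spec()] objects.
#' @param objective_fn Function (named parameter vector) -> numeric
#'   objective vector (all objectives minimized, >= 0).
#' @param pop_size Population size (>= 8); default 32.
#' @param generations Number of generations; default 20.
#' @param seed Integer seed.
#' @param eta_c,eta_m SBX / mutation distribution indices.
#' @param p_mut Per-gene mutation probability; default `1/n_params`.
#' @param init_center Seed one initial individual at the log-space center of
#'   the bounds (the preset model); standard practice in this optimizer
#'   family. Default TRUE.
#' @param init_jitter_sd When non-NULL, initialize the population as the
#'   log-space center plus Gaussian jitter of this sd (log10 units, clipped
#'   to bounds) instead of log-uniform draws: an informative start mirroring
#'   the workflow's preliminary-simulation-derived ranges.
#' @return An `ensemble`: list with `params` (matrix individuals x
#'   parameters), `objectives` (matrix individuals x objectives),
#'   `aggregate` (max z per individual) and `seed`.
#' @export
run_evolution <- function(param_specs, objective_fn, pop_size = 32,
                          generations = 20, seed = 1, eta_c = 10,
                          eta_m = 20, p_mut = NULL, init_center = TRUE,
                          init_jitter_sd = NULL) {
  if (pop_size < 8) stop("population must be >= 8")
  d <- length(param_specs)
  nms <- vapply(param_specs, function(s) s$name, character(1))
  lo <- log10(vapply(param_specs, function(s) s$low, numeric(1)))
  hi <- log10(vapply(param_specs, function(s) s$high, numeric(1)))
  if (is.null(p_mut)) p_mut <- 1 / d
  evaluate <- function(X) {
    res <- apply(X, 1, function(x) objective_fn(stats::setNames(10^x, nms)))
    if (is.matrix(res)) t(res) else matrix(res, ncol = 1)
  }

  with_local_seed(seed, {
    X <- if (is.null(init_jitter_sd))
      matrix(runif(pop_size * d, rep(lo, each = pop_size),
                   rep(hi, each = pop_size)), pop_size, d)
    else matrix(rep((lo + hi) / 2, each = pop_size) +
                  rnorm(pop_size * d, 0, init_jitter_sd), pop_size, d)
    X <- pmin(pmax(X, matrix(rep(lo, each = pop_size), pop_size, d)),
              matrix(rep(hi, each = pop_size), pop_size, d))
    if (init_center) X[1, ] <- (lo + hi) / 2
    F <- evaluate(X)
    for (gen in seq_len(generations)) {
      rank <- .nds_rank(F)
      cd <- .crowding(F)
      ## with the full feature panel the front is high-dimensional and most
      ## individuals are mutually nondominated, so equal ranks break ties on
      ## the aggregate score (max z, then sum of z) before crowding
      agg <- apply(F, 1, max) + 1e-6 * rowSums(F)
      pick <- function() {
        ij <- sample.int(pop_size, 2)
        i <- ij[1]; j <- ij[2]
        if (rank[i] != rank[j]) return(if (rank[i] < rank[j]) i else j)
        if (agg[i] != agg[j]) return(if (agg[i] < agg[j]) i else j)
        if (cd[i] > cd[j]) i else j
      }
      ## SBX crossover + polynomial mutation, vectorized per pair
      child <- matrix(0, pop_size, d)
      for (k in seq(1, pop_size, by = 2)) {
        p1 <- X[pick(), ]; p2 <- X[pick(), ]
        u <- runif(d)
        beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta_c + 1)),
                       (1 / (2 * (1 - u)))^(1 / (eta_c + 1)))
        c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
        c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
        child[k, ] <- c1
        if (k + 1 <= pop_size) child[k + 1, ] <- c2
      }
      mut <- matrix(runif(pop_size * d) < p_mut, pop_size, d)
      if (any(mut)) {
        u <- runif(sum(mut))
        delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta_m + 1)) - 1,
                        1 - (2 * (1 - u))^(1 / (eta_m + 1)))
        span <- matrix(rep(hi - lo, each = pop_size), pop_size, d)
        child[mut] <- child[mut] + delta * span[mut]
      }
      child <- pmin(pmax(child, matrix(rep(lo, each = pop_size),
                                       pop_size, d)),
                    matrix(rep(hi, each = pop_size), pop_size, d))
      Fc <- evaluate(child)
      ## elitist environmental selection over parents + children
      Xall <- rbind(X, child)
      Fall <- rbind(F, Fc)
      rall <- .nds_rank(Fall)
      call_ <- .crowding(Fall)
      aall <- apply(Fall, 1, max) + 1e-6 * rowSums(Fall)
      keep <- order(rall, aall, -call_)[seq_len(pop_size)]
      X <- Xall[keep, , drop = FALSE]
      F <- Fall[keep, , drop = FALSE]
    }
    params <- 10^X
    colnames(params) <- nms
    agg <- apply(F, 1, max)
    structure(list(params = params, objectives = F, aggregate = agg,
                   seed = seed),
              class = "ensemble")
  })
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d individuals, %d parameters, %d objectives\n",
              nrow(x$params), ncol(x$params), ncol(x$objectives)))
  cat(sprintf("  best max-z %.3g, accepted (max z < 3): %d\n",
              min(x$aggregate), sum(x$aggregate < 3)))
  invisible(x)
}

#' Apply the acceptance rule and select the best individuals
#'
#' An individual is acceptable when its worst feature deviation is below 3
#' standard deviations (`max z < 3`, strict). Returns the `k` individuals
#' with the lowest aggregate score (max z, ties broken by sum of z then by
#' archive order, which is seed-stable).
#'
#' @param archive An `ensemble` from [run_evolution()].
#' @param k Number of individuals to keep; default 10.
#' @param threshold Acceptance threshold in sd units; default 3.
#' @return List with `selected` (ensemble subset of size <= k), `accepted`
#'   (logical over the selection) and `n_accepted_total`.
#' @export
select_and_accept <- function(archive, k = 10, threshold = 3) {
  if (!nrow(archive$params)) stop("empty archive")
  agg <- archive$aggregate
  sums <- rowSums(archive$objectives)
  ord <- order(agg, sums)
  keep <- ord[seq_len(min(k, length(ord)))]
  accepted_all <- agg < threshold
  if (!any(accepted_all))
    warning("no individual satisfies the acceptance rule (max z < ",
            threshold, ")")
  sel <- structure(list(params = archive$params[keep, , drop = FALSE],
                        objectives = archive$objectives[keep, , drop = FALSE],
                        aggregate = agg[keep], seed = archive$seed),
                   class = "ensemble")
  list(selected = sel, accepted = agg[keep] < threshold,
       n_accepted_total = sum(accepted_all))
}

## ---- h-current + passive prefit -------------------------------------------

#' Fit h-current kinetics and passive properties to hyperpolarizing traces
#'
#' Simultaneous least-squares minimization of the pointwise voltage error
#' across all traces, over the Borg-Graham Ih parameters (vhalf_l, vhalf_t,
#' a0t, zeta_l, zeta_t, gmt), the Ih peak conductance and the passive
#' properties (capacitance, leak conductance, leak reversal) of an
#' isopotential cell. Deterministic given data and starting point.
#'
#' @param traces List of hyperpolarizing [voltage_trace()] objects (>= 2)
#'   with stimulus metadata.
#' @param init Initial [bg_params()]; default the rat preset (the workflow
#'   starts from the literature kinetics).
#' @param subsample Compare every k-th sample; default 4 (speed).
#' @param n_restarts Extra perturbed starts; default 2.
#' @return List: `ih` (fitted [bg_params()]), `gbar_ih_S_cm2`, `C_pF`,
#'   `g_leak_nS`, `e_leak_mV`, `rms_mV`, `convergence`.
#' @export
prefit_ih <- function(traces, init = ih_params("rat"), subsample = 4,
                      n_restarts = 2) {
  amps <- vapply(traces, function(tr) tr$meta$amplitude_nA, numeric(1))
  if (sum(amps < 0) < 2) stop("need at least 2 hyperpolarizing traces")
  traces <- traces[amps < 0]
  dt <- traces[[1]]$t_ms[2] - traces[[1]]$t_ms[1]

  sim_one <- function(theta, tr) {
    ih <- channel_spec("Ih", list(gate_spec("l", 1L, "borg_graham",
      list(vhalf_l = theta[["vhalf_l"]], vhalf_t = theta[["vhalf_t"]],
           a0t = 10^theta[["log_a0t"]], zeta_l = theta[["zeta_l"]],
           zeta_t = theta[["zeta_t"]], gmt = theta[["gmt"]]))),
      reversal = -30)
    cell <- single_compartment_cell(C_pF = theta[["C_pF"]],
                                    g_leak_nS = theta[["g_leak_nS"]],
                                    e_leak = theta[["e_leak"]], ih = ih,
                                    gbar_ih = 10^theta[["log_gbar_ih"]])
    cell <- inject_step_current(cell, "soma", tr$meta$amplitude_nA,
                                tr$meta$delay_ms, tr$meta$duration_ms)
    simulate(cell, sim_config(t_stop = tr$t_ms[length(tr$t_ms)], dt = dt,
                              settle_ms = 300))
  }
  rms <- function(theta) {
    err2 <- 0
    npt <- 0
    for (tr in traces) {
      sim <- tryCatch(sim_one(theta, tr), error = function(e) NULL)
      if (is.null(sim)) return(1e6)
      idx <- seq(1, length(tr$v_mV), by = subsample)
      err2 <- err2 + sum((sim$v_mV[idx] - tr$v_mV[idx])^2)
      npt <- npt + length(idx)
    }
    sqrt(err2 / npt)
  }

  tr1 <- traces[[which.min(abs(amps[amps < 0]))]]
  base_mean <- mean(tr1$v_mV[tr1$t_ms < tr1$meta$delay_ms])
  theta0 <- c(vhalf_l = init$vhalf_l, vhalf_t = init$vhalf_t,
              log_a0t = log10(init$a0t), zeta_l = init$zeta_l,
              zeta_t = init$zeta_t, gmt = init$gmt,
              log_gbar_ih = -4, C_pF = 150, g_leak_nS = 8,
              e_leak = base_mean)
  lower <- c(-110, -110, -4, 0.5, 0.5, 0.01, -6, 20, 0.5, -90)
  upper <- c(-40, -40, -1, 20, 30, 0.95, -2.5, 600, 60, -50)

  starts <- list(theta0)
  if (n_restarts > 0)
    starts <- c(starts, lapply(seq_len(n_restarts), function(k)
      with_local_seed(k, {
        th <- theta0
        th[c("vhalf_l", "vhalf_t")] <- th[c("vhalf_l", "vhalf_t")] +
          rnorm(2, 0, 4)
        th["log_gbar_ih"] <- th[["log_gbar_ih"]] + rnorm(1, 0, 0.3)
        th
      })))
  best <- NULL
  for (th in starts) {
    fit <- stats::nlminb(th, rms, lower = lower, upper = upper,
                         control = list(eval.max = 800, iter.max = 400,
                                        rel.tol = 1e-10))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  theta <- best$par
  list(ih = bg_params(theta[["vhalf_l"]], theta[["vhalf_t"]],
                      10^theta[["log_a0t"]], theta[["zeta_l"]],
                      theta[["zeta_t"]], theta[["gmt"]]),
       gbar_ih_S_cm2 = 10^theta[["log_gbar_ih"]], C_pF = theta[["C_pF"]],
       g_leak_nS = theta[["g_leak_nS"]], e_leak_mV = theta[["e_leak"]],
       rms_mV = best$objective, convergence = best$convergence)
}
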