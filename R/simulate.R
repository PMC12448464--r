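# Network simulation wrapper around the compiled engine, plus the synaptic
# closed forms (double-exponential kernel, NMDA Mg block) and population
# activity summaries.

#' Normalized double-exponential synaptic kernel
#'
#' \code{u(t) = exp(-t/tau_decay) - exp(-t/tau_rise)} divided by its
#' analytic maximum, so a peak conductance \code{gbar} multiplying the
#' kernel is the true peak of the conductance transient.
#'
#' @param t time since (delayed) presynaptic spike arrival (ms); values
#'   below 0 give 0.
#' @param tau_rise,tau_decay rise and decay time constants (ms),
#'   \code{tau_rise < tau_decay}.
#' @return kernel value in [0, 1].
#' @export
syn_kernel <- function(t, tau_rise, tau_decay) {
  stopifnot(tau_rise < tau_decay)
  u <- exp(-t / tau_decay) - exp(-t / tau_rise)
  u[t < 0] <- 0
  u / syn_kernel_umax(tau_rise, tau_decay)
}

# unnormalized kernel maximum
syn_kernel_umax <- function(tau_rise, tau_decay) {
  tp <- syn_peak_time(tau_rise, tau_decay)
  exp(-tp / tau_decay) - exp(-tp / tau_rise)
}

#' Peak time of the double-exponential kernel
#'
#' Closed form \code{t_peak = ln(tau_decay/tau_rise) * tau_decay * tau_rise /
#' (tau_decay - tau_rise)}.
#'
#' @inheritParams syn_kernel
#' @return peak time (ms).
#' @export
syn_peak_time <- function(tau_rise, tau_decay) {
  stopifnot(tau_rise < tau_decay)
  log(tau_decay / tau_rise) * tau_decay * tau_rise / (tau_decay - tau_rise)
}

#' Voltage dependence of the NMDA receptor (Mg block)
#'
#' \code{s(V) = 1 / (1 + eta * mg_out * exp(-gamma * V))}; with the default
#' constants \code{s(0) = 1/1.28}.
#'
#' @param V membrane potential (mV).
#' @param eta Mg sensitivity (1/mM).
#' @param mg_out extracellular Mg concentration (mM).
#' @param gamma voltage sensitivity (1/mV).
#' @return unblocked fraction in (0, 1).
#' @export
mg_block <- function(V, eta = 0.28, mg_out = 1, gamma = 0.04) {
  1 / (1 + eta * mg_out * exp(-gamma * V))
}

#' Total synaptic current at one instant
#'
#' Reference implementation of the per-neuron current sum used by the
#' engine: for each receptor, \code{g = gbar * u_hat} (NMDA additionally
#' scaled by the Mg block at the current potential) and the current
#' contribution is \code{g * (E_syn - V_m)}, depolarizing when
#' \code{E_syn > V_m}.
#'
#' @param V_m membrane potential (mV).
#' @param receptors data.frame with columns \code{g} (instantaneous peak-
#'   normalized conductance, mS), \code{E_syn} (mV), \code{nmda} (logical).
#' @param mg list with \code{eta}, \code{mg_out}, \code{gamma}.
#' @return total current (uA, internal units).
#' @export
synaptic_current <- function(V_m, receptors,
                             mg = list(eta = 0.28, mg_out = 1, gamma = 0.04)) {
  if (nrow(receptors) == 0) return(0)
  g <- receptors$g
  block <- ifelse(receptors$nmda,
                  mg_block(V_m, mg$eta, mg$mg_out, mg$gamma), 1)
  sum(g * block * (receptors$E_syn - V_m))
}

# assemble the projection list consumed by the compiled engine
engine_projections <- function(net, config) {
  syn <- net$synapses
  pop_index <- c(PP = 0L, GC = 1L, BC = 2L, MC = 3L, HC = 4L)
  dt <- config$engine$dt
  lapply(seq_len(nrow(syn)), function(i) {
    e <- net$edges[[syn$projection[i]]]
    list(pre_pop = unname(pop_index[syn$pre[i]]),
         post_pop = unname(pop_index[syn$post[i]]),
         pre = as.integer(e$pre - 1L), post = as.integer(e$post - 1L),
         gbar = unname(net$weights[syn$projection[i]]) * NS_TO_MS,
         nmda_ratio = if (syn$receptor[i] == "AMPA_NMDA") syn$nmda_ratio[i] else 0,
         E_syn = syn$E_syn[i],
         tau_rise = syn$tau_rise[i], tau_decay = syn$tau_decay[i],
         tau_rise_nmda = syn$tau_rise_nmda[i],
         tau_decay_nmda = syn$tau_decay_nmda[i],
         delay_steps = max(1L, as.integer(round(syn$delay[i] / dt))))
  })
}

#' Simulate the network for one input pattern
#'
#' Synchronous per-step update: deliver delayed spikes, advance synaptic
#' states by exact exponential decay, sum receptor currents (optionally with
#' additive Gaussian current noise), forward-Euler step all neurons, record
#' spikes. Fully reproducible given the seed.
#'
#' @param net a \code{dg_network}.
#' @param pattern a \code{spike_pattern} with \code{n_trains} equal to
#'   \code{net$n_pp} and duration at least the simulated duration.
#' @param config a \code{\link{dg_config}}.
#' @param noise_sigma additive-current-noise level (the experiments use 0,
#'   1, 3, 5); the SD in pA is \code{noise_sigma *
#'   config$perturbations$noise_scale_pa}.
#' @param seed integer seed (only consumed when \code{noise_sigma > 0}).
#' @param duration simulated time (ms); defaults to the pattern duration.
#' @param record_g optional projection name whose summed conductance
#'   time course is recorded per postsynaptic neuron (testing aid).
#' @return object of class \code{dg_sim}: list with \code{spikes} (named
#'   list per population of data.frames \code{neuron}, \code{time}),
#'   \code{window} (analysis window), \code{duration}, \code{sizes},
#'   \code{seed}; plus \code{g_trace} when requested.
#' @export
simulate_network <- function(net, pattern, config = dg_config(),
                             noise_sigma = 0, seed = NULL, duration = NULL,
                             record_g = NULL) {
  stopifnot(inherits(net, "dg_network"), inherits(pattern, "spike_pattern"))
  if (pattern$n_trains != net$n_pp)
    stop("pattern train count does not match the network's PP afferents")
  if (is.null(duration)) duration <- pattern$duration
  if (pattern$duration < duration)
    stop("pattern shorter than the simulated duration")
  eng <- config$engine
  pops <- list(NULL,
               derived_matrix(net$params$GC), derived_matrix(net$params$BC),
               derived_matrix(net$params$MC), derived_matrix(net$params$HC))
  proj <- engine_projections(net, config)
  rec_idx <- -1L
  if (!is.null(record_g)) {
    rec_idx <- match(record_g, net$synapses$projection) - 1L
    if (is.na(rec_idx)) stop("unknown projection: ", record_g)
  }
  noise_sd <- noise_sigma * config$perturbations$noise_scale_pa * PA_TO_UA
  run <- function() dg_simulate_cpp(pops, proj, pattern$trains,
                                    duration, eng$dt, eng$refractory,
                                    eng$exp_cap, noise_sd,
                                    config$mg_block$eta, config$mg_block$mg_out,
                                    config$mg_block$gamma, rec_idx)
  out <- if (noise_sd > 0) with_seed(seed, run()) else run()
  spikes <- lapply(seq_along(NET_POPS), function(k) {
    s <- out$spikes[[k]]
    data.frame(neuron = s$neuron, time = s$time)
  })
  names(spikes) <- NET_POPS
  res <- list(spikes = spikes, window = config$analysis_window,
              duration = duration, sizes = net$sizes, seed = seed)
  if (rec_idx >= 0) res$g_trace <- out$g_trace
  class(res) <- "dg_sim"
  res
}

#' @export
print.dg_sim <- function(x, ...) {
  n <- vapply(x$spikes, nrow, integer(1))
  cat("dg_sim:", x$duration, "ms; spikes:",
      paste(names(n), n, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Firing sparsity of a population
#'
#' \code{1 - f}, where \code{f} is the fraction of the population's neurons
#' that fire at least one spike inside the analysis window.
#'
#' @param sim a \code{dg_sim}.
#' @param population one of \code{"GC"}, \code{"BC"}, \code{"MC"},
#'   \code{"HC"}.
#' @param window analysis window (ms); defaults to the simulation's.
#' @return sparsity in [0, 1].
#' @export
compute_sparsity <- function(sim, population = "GC", window = sim$window) {
  population <- match.arg(population, NET_POPS)
  n <- sim$sizes[[population]]
  if (n == 0) stop("empty population")
  sp <- sim$spikes[[population]]
  active <- unique(sp$neuron[sp$time >= window[1] & sp$time < window[2]])
  1 - length(active) / n
}

#' Per-neuron average firing rates of a simulated population
#'
#' @inheritParams compute_sparsity
#' @return numeric vector (Hz), one entry per neuron.
#' @export
sim_rate_vector <- function(sim, population = "GC", window = sim$window) {
  population <- match.arg(population, NET_POPS)
  n <- sim$sizes[[population]]
  sp <- sim$spikes[[population]]
  keep <- sp$time >= window[1] & sp$time < window[2]
  counts <- tabulate(sp$neuron[keep], nbins = n)
  counts / (diff(window) / 1000)
}

#' Spike trains of a simulated population as a list
#'
#' @inheritParams compute_sparsity
#' @return list of spike-time vectors (ms), one per neuron (empty vectors
#'   for silent neurons).
#' @export
sim_spike_trains <- function(sim, population = "GC") {
  population <- match.arg(population, NET_POPS)
  n <- sim$sizes[[population]]
  sp <- sim$spikes[[population]]
  out <- split(sp$time, factor(sp$neuron, levels = seq_len(n)))
  lapply(out, function(v) sort(unname(v)))
}
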