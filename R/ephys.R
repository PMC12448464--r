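# Electrophysiological characterization protocols.
#
# Six signature measurements are computed per neuron from standard
# current-clamp protocols and validated against subtype-specific ranges:
# membrane time constant (tau_m), sag ratio, input resistance (R_in),
# spike-frequency adaptation (SFA), and firing frequencies at 50 and 150 pA
# (f50, f150). All protocols start after a settling period; the baseline
# voltage is averaged over the 100 ms preceding pulse onset and steady-state
# deflections over the last 10% of the pulse window.

BASELINE_MS <- 100

pulse_response <- function(params, amp_pa, dur_ms, config) {
  sim <- simulate_current_clamp(params, amp_pa, dur_ms, config)
  on_i <- round(sim$onset / sim$dt)
  base_i <- seq(on_i - round(BASELINE_MS / sim$dt) + 1, on_i)
  pulse_i <- seq(on_i + 1, on_i + round(dur_ms / sim$dt))
  ss_i <- pulse_i[seq(ceiling(0.9 * length(pulse_i)), length(pulse_i))]
  in_pulse <- sim$spikes > sim$onset & sim$spikes <= sim$onset + dur_ms
  list(sim = sim, baseline = mean(sim$V[base_i]), pulse_i = pulse_i,
       ss = mean(sim$V[ss_i]), spikes = sim$spikes[in_pulse])
}

#' Membrane time constant
#'
#' Fits a single exponential
#' \code{V(t) = V_inf (1 - exp(-t / tau_m)) + V_0} to the charging transient
#' evoked by a 20 pA, 1500 ms pulse (nonlinear least squares seeded from a
#' log-linear estimate).
#'
#' @param params one-row neuron parameter table.
#' @param config \code{\link{engine_config}}.
#' @return list with \code{tau_m} (ms; \code{NA} if the cell spiked during
#'   the pulse), the fitted \code{V_inf} and \code{V_0} (mV), the fit
#'   residual standard error, and \code{valid}.
#' @export
measure_tau_m <- function(params, config = engine_config()) {
  pr <- pulse_response(params, 20, 1500, config)
  if (length(pr$spikes) > 0)
    return(list(tau_m = NA_real_, V_inf = NA_real_, V_0 = NA_real_,
                sigma = NA_real_, valid = FALSE))
  t <- (seq_along(pr$pulse_i) - 1) * pr$sim$dt
  V <- pr$sim$V[pr$pulse_i]
  fit <- fit_charging_exponential(t, V, pr$baseline)
  c(fit, list(valid = is.finite(fit$tau_m)))
}

# Least-squares fit of V = V_inf (1 - exp(-t/tau)) + V_0.
# Seeded from a log-linear regression of log(1 - deflection/deflection_ss).
fit_charging_exponential <- function(t, V, baseline) {
  V_inf0 <- mean(V[t >= 0.9 * max(t)]) - baseline
  if (abs(V_inf0) < 1e-9)
    return(list(tau_m = NA_real_, V_inf = NA_real_, V_0 = baseline,
                sigma = NA_real_))
  frac <- 1 - (V - baseline) / V_inf0
  ok <- frac > 1e-6 & t > 0 & t < 0.8 * max(t)
  tau0 <- if (sum(ok) > 5) {
    sl <- unname(stats::coef(stats::lm(log(frac[ok]) ~ t[ok]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else max(t) / 5
  } else max(t) / 5
  fit <- tryCatch(
    minpack.lm::nlsLM(V ~ V_inf * (1 - exp(-t / tau_m)) + V_0,
                      start = list(V_inf = V_inf0, tau_m = tau0, V_0 = baseline),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau_m = NA_real_, V_inf = V_inf0, V_0 = baseline,
                sigma = NA_real_))
  cf <- stats::coef(fit)
  list(tau_m = unname(cf["tau_m"]), V_inf = unname(cf["V_inf"]),
       V_0 = unname(cf["V_0"]), sigma = summary(fit)$sigma)
}

#' Sag ratio
#'
#' Ratio of the steady-state to the peak voltage deflection (both measured
#' from the pre-pulse baseline) in response to a -50 pA, 1 s pulse. Without
#' adaptive coupling the charging is monotone and the ratio is 1; subthreshold
#' adaptation produces a depolarizing sag back toward baseline (ratio < 1).
#'
#' @inheritParams measure_tau_m
#' @return list with \code{sag}, \code{V_SS}, \code{V_peak} (deflections, mV)
#'   and \code{valid}.
#' @export
measure_sag <- function(params, config = engine_config()) {
  pr <- pulse_response(params, -50, 1000, config)
  if (length(pr$spikes) > 0)
    return(list(sag = NA_real_, V_SS = NA_real_, V_peak = NA_real_,
                valid = FALSE))
  defl <- pr$sim$V[pr$pulse_i] - pr$baseline
  V_peak <- min(defl)
  V_SS <- pr$ss - pr$baseline
  if (abs(V_peak) < 1e-9)
    return(list(sag = NA_real_, V_SS = V_SS, V_peak = V_peak, valid = FALSE))
  list(sag = V_SS / V_peak, V_SS = V_SS, V_peak = V_peak, valid = TRUE)
}

#' Input resistance
#'
#' Slope of the steady-state voltage deflection versus injected current over
#' a family of 1 s pulses (-40..40 pA in steps of 10 pA; -20..20 pA in steps
#' of 5 pA for HIPP cells, which fire above 20 pA). Amplitudes that evoke
#' spikes are excluded; at least 3 usable points are required.
#'
#' @inheritParams measure_tau_m
#' @param amplitudes optional pA vector overriding the subtype default.
#' @return list with \code{R_in} (MOhm), the per-amplitude deflections, the
#'   excluded amplitudes, and \code{valid}.
#' @export
measure_input_resistance <- function(params, config = engine_config(),
                                     amplitudes = NULL) {
  if (is.null(amplitudes)) {
    amplitudes <- if (identical(params$subtype[1], "HC"))
      seq(-20, 20, 5) else seq(-40, 40, 10)
  }
  defl <- rep(NA_real_, length(amplitudes))
  spiking <- logical(length(amplitudes))
  for (i in seq_along(amplitudes)) {
    pr <- pulse_response(params, amplitudes[i], 1000, config)
    if (length(pr$spikes) > 0) spiking[i] <- TRUE
    else defl[i] <- pr$ss - pr$baseline
  }
  ok <- !spiking
  if (sum(ok) < 3)
    return(list(R_in = NA_real_, amplitudes = amplitudes, deflection = defl,
                excluded = amplitudes[spiking], valid = FALSE))
  slope <- stats::coef(stats::lm(defl[ok] ~ amplitudes[ok]))[2]  # mV/pA = GOhm
  list(R_in = unname(slope) * 1000, amplitudes = amplitudes,
       deflection = defl, excluded = amplitudes[spiking], valid = TRUE)
}

#' Firing frequencies and spike-frequency adaptation
#'
#' Spike counts during 1 s pulses of 50 and 150 pA (f50, f150, in Hz) and the
#' ratio of the first to the last inter-spike interval at 150 pA (SFA).
#' SFA is undefined (NA) with fewer than 3 spikes at 150 pA.
#'
#' @inheritParams measure_tau_m
#' @return list with \code{f50}, \code{f150} (Hz), \code{SFA} and
#'   \code{spikes_150} (ms, relative to pulse onset).
#' @export
measure_firing_and_sfa <- function(params, config = engine_config()) {
  pr50 <- pulse_response(params, 50, 1000, config)
  pr150 <- pulse_response(params, 150, 1000, config)
  sp <- pr150$spikes - pr150$sim$onset
  sfa <- NA_real_
  if (length(sp) >= 3) {
    isi <- diff(sp)
    sfa <- isi[1] / isi[length(isi)]
  }
  list(f50 = length(pr50$spikes), f150 = length(sp), SFA = sfa,
       spikes_150 = sp)
}

#' All six electrophysiological measurements
#'
#' @inheritParams measure_tau_m
#' @return one-row \code{data.frame} with columns \code{tau_m}, \code{sag},
#'   \code{R_in}, \code{SFA}, \code{f50}, \code{f150} (NA marks an undefined
#'   measurement).
#' @export
measure_ephys <- function(params, config = engine_config()) {
  tm <- measure_tau_m(params, config)
  sg <- measure_sag(params, config)
  ri <- measure_input_resistance(params, config)
  ff <- measure_firing_and_sfa(params, config)
  data.frame(tau_m = tm$tau_m, sag = sg$sag, R_in = ri$R_in,
             SFA = ff$SFA, f50 = ff$f50, f150 = ff$f150)
}

MEASUREMENT_NAMES <- c("tau_m", "sag", "R_in", "SFA", "f50", "f150")

#' Validate a neuron's measurements against subtype bounds
#'
#' A model is valid only if all six measurements lie within their respective
#' ranges (strict conjunction); an undefined (NA) measurement fails.
#'
#' @param measurements one-row data.frame from \code{\link{measure_ephys}}.
#' @param bounds bounds table (see \code{\link{dg_config}}), a named list
#'   per subtype of \code{c(lower, upper)} per measurement.
#' @param subtype one of GC, BC, MC, HC.
#' @return list with \code{valid} and a named logical \code{checks}.
#' @export
validate_neuron <- function(measurements, bounds, subtype) {
  subtype <- match.arg(subtype, SUBTYPES)
  b <- bounds[[subtype]]
  stopifnot(all(MEASUREMENT_NAMES %in% names(b)))
  checks <- vapply(MEASUREMENT_NAMES, function(m) {
    v <- measurements[[m]][1]
    lim <- b[[m]]
    !is.na(v) && v >= lim[1] && v <= lim[2]
  }, logical(1))
  list(valid = all(checks), checks = checks)
}
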