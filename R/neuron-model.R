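# Adaptive exponential integrate-and-fire (aEIF) single-neuron model.
#
# Membrane dynamics (all neurons, regardless of subtype):
#   c_m dV/dt = g_l (E_l - V) + g_l Delta_T exp((V - V_th)/Delta_T) + I_syn - w
#   tau_w dw/dt = alpha (V - V_th) - w
# with reset V -> V_reset, w -> w + b whenever V crosses V_th, followed by an
# absolute refractory period. Structure enters through the surface area A:
#   c_m = C_m * A,  g_l = A / R_m.

SUBTYPES <- c("GC", "BC", "MC", "HC")

PARAM_NAMES <- c("C_m", "R_m", "A", "E_l", "V_th", "Delta_T",
                 "V_reset", "tau_w", "alpha", "b")

#' aEIF neuron parameters
#'
#' Build a validated parameter set for one adaptive exponential
#' integrate-and-fire neuron.
#'
#' @param subtype one of \code{"GC"}, \code{"BC"}, \code{"MC"}, \code{"HC"}
#'   (granule, basket, mossy, HIPP cell).
#' @param C_m specific membrane capacitance (uF/cm^2).
#' @param R_m specific membrane resistance (kOhm cm^2).
#' @param A surface area (cm^2).
#' @param E_l leak reversal potential (mV).
#' @param V_th spike threshold (mV).
#' @param Delta_T slope factor of the exponential spike-initiation term (mV).
#' @param V_reset post-spike reset voltage (mV).
#' @param tau_w adaptation time constant (ms).
#' @param alpha subthreshold adaptive coupling (uS).
#' @param b spike-triggered adaptation increment (nA).
#' @return A one-row \code{data.frame} with the ten parameters plus the
#'   subtype, suitable for stacking into population tables.
#' @export
neuron_params <- function(subtype, C_m, R_m, A, E_l, V_th, Delta_T,
                          V_reset, tau_w, alpha, b) {
  subtype <- match.arg(subtype, SUBTYPES)
  p <- data.frame(subtype = subtype, C_m = C_m, R_m = R_m, A = A, E_l = E_l,
                  V_th = V_th, Delta_T = Delta_T, V_reset = V_reset,
                  tau_w = tau_w, alpha = alpha, b = b,
                  stringsAsFactors = FALSE)
  check_neuron_params(p)
  p
}

check_neuron_params <- function(p) {
  stopifnot(all(PARAM_NAMES %in% names(p)))
  if (any(p$C_m <= 0) || any(p$R_m <= 0) || any(p$A <= 0))
    stop("C_m, R_m and A must be positive")
  if (any(p$Delta_T <= 0) || any(p$tau_w <= 0))
    stop("Delta_T and tau_w must be positive")
  if (any(p$V_reset > p$V_th))
    stop("V_reset must not exceed V_th")
  invisible(p)
}

#' Derived membrane coefficients
#'
#' Scale the specific parameters by surface area: \code{c_m = C_m * A} (uF)
#' and \code{g_l = A / R_m} (mS).
#'
#' @param params a parameter row or table as returned by
#'   \code{\link{neuron_params}}.
#' @return A list with elements \code{c_m} (uF) and \code{g_l} (mS),
#'   vectorized over rows.
#' @export
derive_membrane_coefficients <- function(params) {
  if (any(params$A <= 0) || any(params$R_m <= 0))
    stop("invalid parameters: A and R_m must be positive")
  list(c_m = params$C_m * params$A, g_l = params$A / params$R_m)
}

# 9-column engine matrix in internal units; column order is shared with the
# C++ engine: c_m, g_l, E_l, V_th, Delta_T, V_reset, tau_w, alpha, b
derived_matrix <- function(params) {
  check_neuron_params(params)
  co <- derive_membrane_coefficients(params)
  m <- cbind(c_m = co$c_m, g_l = co$g_l, E_l = params$E_l,
             V_th = params$V_th, Delta_T = params$Delta_T,
             V_reset = params$V_reset, tau_w = params$tau_w,
             alpha = params$alpha * US_TO_MS, b = params$b * NA_TO_UA)
  m
}

#' Advance one neuron by a single time step
#'
#' Pure-R forward-Euler step of the aEIF dynamics, including spike detection,
#' reset, and refractory handling. The compiled engine implements the same
#' update; this function exists as a transparent reference for single-step
#' reasoning and testing.
#'
#' @param state list with \code{V_m} (mV), \code{w} (nA-scale, internal uA)
#'   and \code{refractory_remaining} (ms).
#' @param params one-row parameter table (\code{\link{neuron_params}}).
#' @param I_syn_total total synaptic/injected current (uA, internal units).
#' @param dt step (ms).
#' @param config \code{\link{engine_config}}.
#' @return list with the updated \code{state} and a logical \code{spiked}.
#' @export
step_neuron <- function(state, params, I_syn_total, dt = 0.1,
                        config = engine_config(dt = dt)) {
  stopifnot(dt > 0)
  m <- derived_matrix(params)[1, ]
  V <- state$V_m; w <- state$w; refrac <- state$refractory_remaining
  spiked <- FALSE
  if (refrac > 0) {
    w <- w + (m["alpha"] * (V - m["V_th"]) - w) / m["tau_w"] * dt
    refrac <- max(0, refrac - dt)
  } else {
    arg <- min((V - m["V_th"]) / m["Delta_T"], config$exp_cap)
    dV <- (m["g_l"] * (m["E_l"] - V) +
             m["g_l"] * m["Delta_T"] * exp(arg) + I_syn_total - w) / m["c_m"] * dt
    dw <- (m["alpha"] * (V - m["V_th"]) - w) / m["tau_w"] * dt
    V <- V + dV
    w <- w + dw
    if (!is.finite(V) || !is.finite(w))
      stop("non-finite state after step")
    if (V >= m["V_th"]) {
      spiked <- TRUE
      V <- m["V_reset"]
      w <- w + m["b"]
      refrac <- config$refractory
    }
  }
  list(state = list(V_m = unname(V), w = unname(w),
                    refractory_remaining = unname(refrac)),
       spiked = spiked)
}

#' Current-clamp simulation of a single neuron
#'
#' Simulates the aEIF model under an injected current waveform, preceded by a
#' settling period at zero current during which the model relaxes to rest.
#'
#' @param params one-row parameter table.
#' @param current_pa injected current: either a single number (constant over
#'   \code{duration}) or a numeric vector sampled at \code{config$dt}
#'   covering \code{[0, duration)}; in pA.
#' @param duration stimulus duration (ms).
#' @param config \code{\link{engine_config}}; \code{config$settle} ms of zero
#'   current precede the stimulus.
#' @return list with \code{time} (ms, from the start of the settling period),
#'   \code{V} (mV), \code{spikes} (ms, absolute), \code{onset} (stimulus
#'   onset time, ms) and \code{dt}.
#' @export
simulate_current_clamp <- function(params, current_pa, duration,
                                   config = engine_config()) {
  dt <- config$dt
  n_stim <- round(duration / dt)
  if (length(current_pa) == 1L) current_pa <- rep(current_pa, n_stim)
  if (length(current_pa) != n_stim)
    stop("current waveform must cover [0, duration) at dt resolution")
  n_settle <- round(config$settle / dt)
  I <- c(rep(0, n_settle), current_pa) * PA_TO_UA
  m <- derived_matrix(params)[1, ]
  out <- aeif_clamp_cpp(m, I, dt, config$refractory, config$exp_cap,
                        V0 = m[["E_l"]], w0 = 0)
  list(time = seq_len(length(I)) * dt, V = out$V, spikes = out$spikes,
       onset = config$settle, dt = dt)
}
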