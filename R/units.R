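# Internal unit system. The engine works in a coherent set of units
# (mV, ms, uF, mS, uA) so that the membrane equation needs no conversion
# factors. User-facing quantities keep the conventions of the
# electrophysiology literature: injected currents in pA, synaptic peak
# conductances in nS, adaptive coupling in uS, spike-triggered adaptation
# in nA.

PA_TO_UA <- 1e-6
NS_TO_MS <- 1e-6
US_TO_MS <- 1e-3
NA_TO_UA <- 1e-3

#' Engine configuration
#'
#' Numerical settings of the forward-Euler integration engine.
#'
#' @param dt integration step (ms).
#' @param refractory absolute refractory period imposed after each spike (ms).
#'   During the refractory window the membrane potential is held at the reset
#'   voltage while the adaptation variable keeps evolving; synaptic states
#'   keep evolving but do not move the membrane.
#' @param exp_cap ceiling on the argument of the exponential spike-initiation
#'   term, preventing numeric overflow within the step on which a spike is
#'   detected.
#' @param settle settling time simulated before any stimulus so the model
#'   relaxes to its resting state (ms).
#' @return A list of class \code{dg_engine_config}.
#' @export
engine_config <- function(dt = 0.1, refractory = 5, exp_cap = 10, settle = 500) {
  stopifnot(dt > 0, refractory >= 0, settle >= 0)
  structure(list(dt = dt, refractory = refractory, exp_cap = exp_cap,
                 settle = settle),
            class = "dg_engine_config")
}
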