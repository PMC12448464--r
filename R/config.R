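# Default model configuration.
#
# The dentate gyrus circuit: perforant-path (PP) afferents excite granule
# cells (GC) and HIPP cells (HC); granule cells excite basket (BC) and mossy
# cells (MC); mossy cells excite granule and basket cells; basket and HIPP
# cells inhibit granule cells. Eight projection classes in total.
#
# Population counts, the NMDA Mg-block constants, the 8 Hz / 700-train input
# statistics, the refractory period and the integration step follow the
# modeling literature for this circuit. Per-subtype aEIF parameter defaults,
# their search ranges, the electrophysiological validation ranges, synaptic
# kinetics, delays and connection probabilities are implementer-chosen
# defaults tuned to produce subtype-appropriate physiology; they are plain
# config entries and can be replaced wholesale (see dg_config_write /
# dg_config_read).

PROJECTIONS <- c("PP_GC", "PP_HC", "GC_BC", "GC_MC",
                 "MC_GC", "MC_BC", "BC_GC", "HC_GC")

#' Default model configuration
#'
#' Assemble the full configuration: engine settings, population sizes, per
#' subtype aEIF defaults and sampling ranges, electrophysiological bounds,
#' the synapse table (kinetics, delays, connection probabilities, hand-tuned
#' default weights), weight search ranges, pattern-separation validation
#' bounds, input-pattern settings and perturbation settings.
#'
#' @param profile \code{"full"} for the complete circuit (3600 GC, 500 BC,
#'   180 MC, 50 HC, 700 PP afferents) or \code{"reduced"} for a desk-scale
#'   circuit with the same architecture at one-tenth the population sizes
#'   (360/50/18/5, 140 PP afferents) used for fast experimentation and
#'   testing. Connection probabilities in the reduced profile are scaled up
#'   so expected in-degrees stay comparable.
#' @return A nested list of class \code{dg_config}.
#' @export
dg_config <- function(profile = c("full", "reduced")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    engine = list(dt = 0.1, refractory = 5, exp_cap = 10, settle = 500),
    mg_block = list(eta = 0.28, mg_out = 1, gamma = 0.04),
    populations = c(GC = 3600L, BC = 500L, MC = 180L, HC = 50L),
    input = list(n_trains = 700L, rate_hz = 8, duration_ms = 2000,
                 betas = seq(0, 1, 0.1), distinctness_r = 0.1),
    analysis_window = c(500, 2000),
    wiring = "fixed_in",
    neuron_defaults = default_neuron_params(),
    neuron_ranges = default_neuron_ranges(),
    ephys_bounds = default_ephys_bounds(),
    synapses = default_synapses("full"),
    weight_ranges = default_weight_ranges("full"),
    ps_bounds = list(A_PS_min = 0.15, A_PC_max = 0.02,
                     T_PCPS_max = 0.25, PS_max_min = 0.2),
    perturbations = list(levels = c(low = 1, medium = 3, high = 5),
                         jitter_scale = 0.02, noise_scale_pa = 10)
  )
  if (profile == "reduced") {
    cfg$populations <- c(GC = 360L, BC = 50L, MC = 18L, HC = 5L)
    cfg$input$n_trains <- 280L
    # with fewer trains the sampling error of the base-pattern correlation
    # is larger, so the distinctness criterion is tightened accordingly
    cfg$input$distinctness_r <- 0.05
    cfg$synapses <- default_synapses("reduced")
    cfg$weight_ranges <- default_weight_ranges("reduced")
  }
  class(cfg) <- "dg_config"
  cfg
}

# Hand-tuned aEIF defaults per subtype (user units; see neuron_params).
# GC: slow, high-resistance, adapting, sparse firing. BC: fast, low
# resistance, non-adapting. MC: intermediate with prominent sag. HC: very
# high resistance, fires for small currents.
default_neuron_params <- function() {
  list(
    GC = neuron_params("GC", C_m = 1, R_m = 23, A = 1e-4, E_l = -75,
                       V_th = -52, Delta_T = 2, V_reset = -62,
                       tau_w = 120, alpha = 5e-4, b = 0.026),
    BC = neuron_params("BC", C_m = 1, R_m = 10, A = 0.8e-4, E_l = -65,
                       V_th = -48, Delta_T = 1, V_reset = -58,
                       tau_w = 15, alpha = 1e-4, b = 0),
    MC = neuron_params("MC", C_m = 1, R_m = 20, A = 1e-4, E_l = -68,
                       V_th = -50, Delta_T = 2, V_reset = -60,
                       tau_w = 150, alpha = 8e-4, b = 0.015),
    HC = neuron_params("HC", C_m = 1, R_m = 35, A = 0.55e-4, E_l = -70,
                       V_th = -52, Delta_T = 2, V_reset = -60,
                       tau_w = 100, alpha = 3e-4, b = 0.01)
  )
}

# Uniform sampling ranges for the stochastic search. Nine of the ten
# parameters are sampled; the specific capacitance C_m is held at its
# biologically near-universal value of 1 uF/cm^2 and excluded from the
# search. Ranges are multiplicative bands around the subtype defaults for
# scale parameters and additive bands for voltages.
default_neuron_ranges <- function() {
  lapply(default_neuron_params(), function(p) {
    r <- list()
    for (nm in c("R_m", "A", "Delta_T", "tau_w", "alpha", "b")) {
      v <- p[[nm]]
      r[[nm]] <- if (v == 0) c(0, 0.01) else c(0.75 * v, 1.25 * v)
    }
    for (nm in c("E_l", "V_th")) r[[nm]] <- c(p[[nm]] - 3, p[[nm]] + 3)
    # keep V_reset below every admissible V_th draw
    r$V_reset <- c(p$V_reset - 3, min(p$V_reset + 3, p$V_th - 3.5))
    r
  })
}

# Electrophysiological validation ranges per subtype (tau_m ms, sag ratio,
# R_in MOhm, SFA ratio, f50 & f150 Hz). The granule-cell bands are kept
# deliberately tight: the validation step is what bounds the functional
# (excitability) spread of the heterogeneous population while the sampled
# parameters themselves remain free to compensate across dimensions.
default_ephys_bounds <- function() {
  list(
    GC = list(tau_m = c(15, 35), sag = c(0.85, 1), R_in = c(170, 260),
              SFA = c(0.2, 0.8), f50 = c(0, 2), f150 = c(12, 20)),
    BC = list(tau_m = c(5, 18), sag = c(0.9, 1), R_in = c(60, 220),
              SFA = c(0.5, 1.05), f50 = c(0, 10), f150 = c(10, 80)),
    MC = list(tau_m = c(12, 35), sag = c(0.8, 1), R_in = c(100, 350),
              SFA = c(0.1, 0.9), f50 = c(0, 15), f150 = c(5, 60)),
    HC = list(tau_m = c(20, 60), sag = c(0.85, 1), R_in = c(350, 1000),
              SFA = c(0.1, 1.0), f50 = c(5, 60), f150 = c(10, 120))
  )
}

# The eight projection classes with receptor kinetics (ms), reversal
# potentials (mV), delays (ms), connection probabilities and hand-tuned
# default peak conductances (nS). Excitatory projections carry colocalized
# AMPA and NMDA receptors (NMDA peak conductance = nmda_ratio * AMPA peak
# conductance); inhibitory projections carry GABA-A receptors (E = -90 mV).
default_synapses <- function(profile) {
  s <- data.frame(
    projection = PROJECTIONS,
    pre  = c("PP", "PP", "GC", "GC", "MC", "MC", "BC", "HC"),
    post = c("GC", "HC", "BC", "MC", "GC", "BC", "GC", "GC"),
    receptor = c("AMPA_NMDA", "AMPA_NMDA", "AMPA_NMDA", "AMPA_NMDA",
                 "AMPA_NMDA", "AMPA_NMDA", "GABAA", "GABAA"),
    E_syn = c(0, 0, 0, 0, 0, 0, -90, -90),
    tau_rise = c(0.5, 0.5, 0.3, 0.5, 0.5, 0.5, 0.4, 0.9),
    tau_decay = c(3.5, 3.5, 2.5, 3.0, 3.0, 3.0, 6.0, 11.0),
    tau_rise_nmda = rep(5, 8),
    tau_decay_nmda = rep(50, 8),
    nmda_ratio = c(rep(0.3, 6), 0, 0),
    delay = c(1.5, 1.5, 0.8, 1.0, 1.0, 1.0, 0.8, 1.0),
    # full-scale probabilities; chosen to give sparse, input-selective
    # granule-cell afferents (about 10 PP inputs per GC) and convergent
    # interneuron wiring
    prob = c(0.0143, 0.10, 0.03, 0.03, 0.04, 0.04, 0.06, 0.08),
    gbar = c(3.0, 0.35, 6.0, 3.0, 0.15, 0.3, 10.0, 1.8),
    stringsAsFactors = FALSE
  )
  if (profile == "reduced") {
    # preserve expected in-degrees at the reduced population sizes
    # (280 PP, 360 GC, 50 BC, 18 MC, 5 HC)
    s$prob <- c(10 / 280, 70 / 280, 108 / 360, 108 / 360,
                7 / 18, 7 / 18, 30 / 50, 4 / 5)
  }
  s
}

# Uniform sampling ranges (nS) for the network-level weight search: a band
# around the hand-tuned default conductances, mirroring the cellular search
# where bounds are set around the default model's parameters.
default_weight_ranges <- function(profile) {
  g <- default_synapses(profile)$gbar
  rng <- lapply(seq_along(g), function(i) c(0.5 * g[i], 1.5 * g[i]))
  names(rng) <- PROJECTIONS
  rng
}

#' @export
print.dg_config <- function(x, ...) {
  cat("dgsep configuration (profile:", x$profile, ")\n")
  cat("  populations:", paste(names(x$populations), x$populations,
                              sep = "=", collapse = ", "), "\n")
  cat("  PP afferents:", x$input$n_trains, "at", x$input$rate_hz, "Hz\n")
  cat("  engine: dt =", x$engine$dt, "ms, refractory =",
      x$engine$refractory, "ms\n")
  invisible(x)
}

#' Write / read a configuration as YAML
#'
#' @param cfg a \code{dg_config} list.
#' @param path file path.
#' @return \code{dg_config_read} returns the configuration list.
#' @export
dg_config_write <- function(cfg, path) {
  c2 <- unclass(cfg)
  c2$neuron_defaults <- lapply(c2$neuron_defaults, as.list)
  c2$synapses <- as.list(c2$synapses)
  c2$populations <- as.list(c2$populations)
  yaml::write_yaml(c2, path, precision = 15)
  invisible(path)
}

#' @rdname dg_config_write
#' @export
dg_config_read <- function(path) {
  c2 <- yaml::read_yaml(path)
  c2$neuron_defaults <- lapply(c2$neuron_defaults, function(p)
    do.call(neuron_params, p))
  c2$synapses <- as.data.frame(c2$synapses, stringsAsFactors = FALSE)
  c2$populations <- unlist(c2$populations)
  c2$input$betas <- as.numeric(c2$input$betas)
  c2$analysis_window <- as.numeric(c2$analysis_window)
  c2$perturbations$levels <- unlist(c2$perturbations$levels)
  class(c2) <- "dg_config"
  c2
}

# Run-to-run provenance: stable polynomial hash of the deparsed
# configuration (no dependency on external digest packages).
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Local, restore-on-exit seeding so library functions do not clobber the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a bounded child seed from a master seed and a stream label.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (seed * 48271 + k * 1299721) %% 2147483562 + 1
}
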