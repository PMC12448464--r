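# Shared fixtures, built once per test run and cached. The expensive pieces
# (validated neuron populations, a reduced network-weight search) are reused
# across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

test_cfg <- function() fixture("cfg", function() dg_config("reduced"))

# validated heterogeneous populations at the reduced scale
test_pops <- function() fixture("pops", function() {
  cfg <- test_cfg()
  searches <- search_all_subtypes(cfg, n = c(GC = 1500, BC = 120, MC = 50,
                                             HC = 30), seed = 101)
  lapply(searches, valid_models)
})

# a reduced weight-space search shared by the pattern-separation and
# perturbation tests
test_search <- function() fixture("search", function() {
  run_network_mpmoss(test_pops(), test_cfg(), n_candidates = 10, seed = 301)
})

# a tiny all-to-all network scaffold for engine-level tests; all weights
# default to zero so individual projections can be switched on
tiny_network <- function(weights = NULL, n_gc = 4, n_pp = 3,
                         nmda = FALSE) {
  cfg <- dg_config("reduced")
  cfg$populations <- c(GC = as.integer(n_gc), BC = 1L, MC = 1L, HC = 1L)
  cfg$input$n_trains <- as.integer(n_pp)
  cfg$synapses$prob <- rep(1, 8)
  if (!nmda) cfg$synapses$nmda_ratio <- rep(0, 8)
  def <- dgsep:::default_neuron_params()
  pops <- lapply(def, function(p) p[rep(1, max(n_gc, 2)), ])
  w <- stats::setNames(rep(0, 8), cfg$synapses$projection)
  if (!is.null(weights)) w[names(weights)] <- weights
  list(net = build_network(pops, cfg, weights = w, seed = 1), cfg = cfg)
}

# a deterministic hand-written spike pattern
manual_pattern <- function(trains, duration = 2000) {
  structure(list(trains = trains, n_trains = length(trains),
                 duration = duration, rate_hz = NA_real_, beta = 0,
                 seed = NULL),
            class = "spike_pattern")
}

# passive cell: no adaptation, tiny slope factor, threshold far away
passive_params <- function(R_m = 20, A = 1e-4, C_m = 1, E_l = -70) {
  neuron_params("GC", C_m = C_m, R_m = R_m, A = A, E_l = E_l, V_th = 100,
                Delta_T = 0.5, V_reset = -75, tau_w = 100, alpha = 0, b = 0)
}
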