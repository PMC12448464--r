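# Network-level experiments: the stochastic search over the eight synaptic
# weights, interneuron-deletion studies, and jitter/noise robustness studies
# comparing heterogeneous networks with their homogeneous counterparts.

# S_out curves (r and R) for a list of per-beta GC spike-train lists,
# relative to the first entry; C_0 is computed once.
output_similarity <- function(trains_by_beta, window, rate_dt = 1) {
  rates <- lapply(trains_by_beta, function(tr) {
    counts <- lengths(lapply(tr, function(v)
      v[v >= window[1] & v < window[2]]))
    counts / (diff(window) / 1000)
  })
  F0 <- rates[[1]]
  s_r <- vapply(rates, function(Fb) rate_correlation(F0, Fb), numeric(1))
  C0 <- pairwise_pearson(smooth_rates(trains_by_beta[[1]], window, rate_dt))
  ut <- upper.tri(C0)
  a <- C0[ut]
  s_R <- vapply(trains_by_beta, function(tr) {
    Cb <- pairwise_pearson(smooth_rates(tr, window, rate_dt))
    b <- Cb[ut]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  list(r = s_r, R = s_R)
}

# Input similarity curves (r and R) for a morphed pattern set.
input_similarity <- function(patterns, window, rate_dt = 1) {
  F0 <- pattern_rate_map(patterns[[1]], window)
  s_r <- vapply(patterns, function(P)
    rate_correlation(F0, pattern_rate_map(P, window)), numeric(1))
  s_R <- vapply(patterns, function(P)
    instantaneous_rate_correlation(patterns[[1]]$trains, P$trains, window,
                                   rate_dt), numeric(1))
  list(r = s_r, R = s_R)
}

# Present all patterns to one network; return GC trains per beta plus the
# sparsity (all populations) under the first pattern.
present_patterns <- function(net, patterns, config, noise_sigma = 0,
                             seed = NULL) {
  gc_trains <- vector("list", length(patterns))
  sparsity <- NULL
  for (j in seq_along(patterns)) {
    sim <- simulate_network(net, patterns[[j]], config,
                            noise_sigma = noise_sigma,
                            seed = child_seed(seed, j))
    gc_trains[[j]] <- sim_spike_trains(sim, "GC")
    if (j == 1)
      sparsity <- vapply(NET_POPS, function(p)
        compute_sparsity(sim, p), numeric(1))
  }
  list(gc_trains = gc_trains, sparsity = sparsity)
}

# Full pattern-separation read-out for one network: simulate all patterns,
# build both S_out-vs-S_in curves, quantify and validate.
network_ps <- function(net, patterns, s_in, config, noise_sigma = 0,
                       seed = NULL, rate_dt = 1) {
  pres <- present_patterns(net, patterns, config, noise_sigma, seed)
  s_out <- output_similarity(pres$gc_trains, config$analysis_window, rate_dt)
  ps_r <- ps_from_curve(s_in$r, s_out$r)
  ps_R <- ps_from_curve(s_in$R, s_out$R)
  val <- validate_network_ps(ps_r, ps_R, config$ps_bounds)
  list(ps_r = ps_r, ps_R = ps_R, valid = val$valid, checks = val$checks,
       s_out = s_out, sparsity = pres$sparsity)
}

measurement_row <- function(ps, network_id, condition, metric) {
  m <- ps$measurements
  if (is.null(m))
    return(data.frame(network = network_id, condition = condition,
                      metric = metric, A_PS = NA_real_, A_PC = NA_real_,
                      T_PCPS = NA_real_, PS_max = NA_real_))
  data.frame(network = network_id, condition = condition, metric = metric,
             A_PS = m$A_PS, A_PC = m$A_PC, T_PCPS = m$T_PCPS,
             PS_max = m$PS_max)
}

#' Stochastic search over the synaptic weight space
#'
#' Builds one heterogeneous network (neuron assignment and adjacency are
#' drawn once and shared across every candidate), draws candidate weight
#' vectors uniformly from the per-projection ranges, presents the full
#' morphed pattern set to each candidate, quantifies pattern separation with
#' both correlation metrics, and validates each candidate against the
#' pattern-separation bounds (eight checks).
#'
#' @param populations named list of parameter tables (e.g. valid models from
#'   \code{\link{search_all_subtypes}}) with enough rows per subtype.
#' @param config \code{\link{dg_config}}.
#' @param n_candidates number of random weight vectors.
#' @param seed master seed (neuron assignment, wiring, patterns and weight
#'   draws all derive child seeds from it).
#' @param patterns optional pre-built morphed pattern list (defaults to a
#'   fresh \code{\link{make_pattern_set}} at the config input settings).
#' @param rate_dt sampling step (ms) of the instantaneous-rate metric.
#' @return object of class \code{dg_network_search}: list with
#'   \code{weights} (candidates x 8 matrix, nS), \code{measurements} (long
#'   data.frame over candidates and metrics), \code{valid},
#'   \code{sparsity} (candidates x 4), \code{base_network},
#'   \code{patterns}, \code{s_in}, \code{n_candidates}, \code{seed},
#'   \code{config}.
#' @export
run_network_mpmoss <- function(populations, config = dg_config("reduced"),
                               n_candidates = 100, seed = 1,
                               patterns = NULL, rate_dt = 1) {
  stopifnot(n_candidates >= 1)
  base_net <- build_network(populations, config, seed = child_seed(seed, 1))
  if (is.null(patterns)) {
    ps_set <- make_pattern_set(config$input$n_trains, config$input$rate_hz,
                               config$input$duration_ms,
                               seed = child_seed(seed, 2),
                               betas = config$input$betas,
                               distinctness_r = config$input$distinctness_r)
    patterns <- ps_set$patterns
  }
  s_in <- input_similarity(patterns, config$analysis_window, rate_dt)
  rng <- config$weight_ranges
  W <- with_seed(child_seed(seed, 3), {
    vapply(PROJECTIONS, function(pj)
      stats::runif(n_candidates, rng[[pj]][1], rng[[pj]][2]),
      numeric(n_candidates))
  })
  W <- matrix(W, nrow = n_candidates,
              dimnames = list(NULL, PROJECTIONS))
  rows <- list()
  valid <- logical(n_candidates)
  sparsity <- matrix(NA_real_, n_candidates, 4,
                     dimnames = list(NULL, NET_POPS))
  for (i in seq_len(n_candidates)) {
    net_i <- base_net
    net_i$weights[] <- W[i, ]
    res <- tryCatch(
      network_ps(net_i, patterns, s_in, config, rate_dt = rate_dt),
      error = function(e) NULL)
    if (is.null(res)) next  # failed candidate recorded invalid
    valid[i] <- res$valid
    sparsity[i, ] <- res$sparsity
    rows[[length(rows) + 1]] <- rbind(
      measurement_row(res$ps_r, i, "baseline", "r"),
      measurement_row(res$ps_R, i, "baseline", "R"))
  }
  structure(list(weights = W, measurements = do.call(rbind, rows),
                 valid = valid, sparsity = sparsity,
                 base_network = base_net, patterns = patterns, s_in = s_in,
                 n_candidates = n_candidates, N_valid = sum(valid),
                 seed = seed, rate_dt = rate_dt, config = config),
            class = "dg_network_search")
}

#' @export
print.dg_network_search <- function(x, ...) {
  cat(sprintf("dg_network_search: %d / %d candidate networks valid\n",
              x$N_valid, x$n_candidates))
  invisible(x)
}

# reconstruct candidate i's network from a search result
candidate_network <- function(search, i) {
  net <- search$base_network
  net$weights[] <- search$weights[i, ]
  net
}

#' Interneuron-deletion study
#'
#' For every valid network of a search, deletes each interneuron subtype in
#' turn (weights of all its synapses set to zero), re-presents the full
#' pattern set, and reports the pattern-separation measurements and
#' per-population sparsity against baseline. Produces exactly
#' \code{3 * N_valid} deletion conditions.
#'
#' @param search a \code{dg_network_search}.
#' @param subtypes interneuron classes to delete.
#' @return list with \code{measurements} (long data.frame: network,
#'   condition, metric, four measurements) and \code{sparsity} (long
#'   data.frame: network, condition, population, sparsity), baseline rows
#'   included.
#' @export
deletion_study <- function(search, subtypes = c("BC", "MC", "HC")) {
  stopifnot(inherits(search, "dg_network_search"))
  ids <- which(search$valid)
  if (length(ids) == 0) stop("no valid networks in the search result")
  cfg <- search$config
  meas <- list(); spars <- list()
  for (i in ids) {
    meas[[length(meas) + 1]] <- search$measurements[
      search$measurements$network == i, ]
    spars[[length(spars) + 1]] <- data.frame(
      network = i, condition = "baseline", population = NET_POPS,
      sparsity = unname(search$sparsity[i, ]))
    for (st in subtypes) {
      net_d <- delete_subtype(candidate_network(search, i), st)
      res <- network_ps(net_d, search$patterns, search$s_in, cfg,
                        rate_dt = search$rate_dt)
      cond <- paste0("delete_", st)
      meas[[length(meas) + 1]] <- rbind(
        measurement_row(res$ps_r, i, cond, "r"),
        measurement_row(res$ps_R, i, cond, "R"))
      spars[[length(spars) + 1]] <- data.frame(
        network = i, condition = cond, population = NET_POPS,
        sparsity = unname(res$sparsity))
    }
  }
  list(measurements = do.call(rbind, meas),
       sparsity = do.call(rbind, spars),
       n_conditions = length(ids) * length(subtypes))
}

#' Robustness to synaptic jitter and current noise
#'
#' For each selected network (and, optionally, its homogeneous counterpart
#' with conserved connectivity), applies weight jitter, additive current
#' noise, or both at the given levels, re-measures pattern separation, and
#' reports the percentage change of every measurement relative to the same
#' network without perturbation.
#'
#' @param search a \code{dg_network_search}.
#' @param networks candidate indices (default: all valid).
#' @param modes subset of \code{"jitter"}, \code{"noise"}, \code{"both"}.
#' @param levels named or plain numeric vector of sigma levels (the study
#'   uses low = 1, medium = 3, high = 5).
#' @param cohorts \code{"heterogeneous"}, \code{"homogeneous"} or both.
#' @param seed master seed for the perturbation draws.
#' @return long data.frame: network, cohort, mode, level, metric,
#'   measurement, baseline value, perturbed value, percent change.
#' @export
robustness_study <- function(search, networks = which(search$valid),
                             modes = c("jitter", "noise", "both"),
                             levels = c(low = 1, medium = 3, high = 5),
                             cohorts = c("heterogeneous", "homogeneous"),
                             seed = 1) {
  stopifnot(inherits(search, "dg_network_search"))
  cfg <- search$config
  modes <- match.arg(modes, c("jitter", "noise", "both"), several.ok = TRUE)
  cohorts <- match.arg(cohorts, c("heterogeneous", "homogeneous"),
                       several.ok = TRUE)
  if (is.null(names(levels))) names(levels) <- as.character(levels)
  out <- list()
  for (i in networks) {
    for (coh in cohorts) {
      net <- candidate_network(search, i)
      if (coh == "homogeneous") net <- make_homogeneous(net)
      base <- network_ps(net, search$patterns, search$s_in, cfg,
                         rate_dt = search$rate_dt)
      base_tab <- rbind(measurement_row(base$ps_r, i, "baseline", "r"),
                        measurement_row(base$ps_R, i, "baseline", "R"))
      for (mode in modes) {
        for (li in seq_along(levels)) {
          sg <- levels[[li]]
          net_p <- net
          if (mode %in% c("jitter", "both"))
            net_p <- jitter_weights(net_p, sg,
                                    seed = child_seed(seed, i * 100 + li),
                                    scale = cfg$perturbations$jitter_scale)
          noise_sg <- if (mode %in% c("noise", "both")) sg else 0
          res <- network_ps(net_p, search$patterns, search$s_in, cfg,
                            noise_sigma = noise_sg,
                            seed = child_seed(seed, i * 100 + 50 + li),
                            rate_dt = search$rate_dt)
          pert_tab <- rbind(measurement_row(res$ps_r, i, "pert", "r"),
                            measurement_row(res$ps_R, i, "pert", "R"))
          for (metric in c("r", "R")) {
            b <- base_tab[base_tab$metric == metric, ]
            p <- pert_tab[pert_tab$metric == metric, ]
            for (ms in c("A_PS", "A_PC", "T_PCPS", "PS_max")) {
              bv <- b[[ms]]; pv <- p[[ms]]
              # a zero baseline with an unchanged value is a 0% change; a
              # change away from a zero baseline is undefined
              pct <- if (is.na(bv) || is.na(pv)) NA_real_
                     else if (bv == 0 && pv == bv) 0
                     else if (bv == 0) NA_real_
                     else 100 * (pv - bv) / abs(bv)
              out[[length(out) + 1]] <- data.frame(
                network = i, cohort = coh, mode = mode,
                level = names(levels)[li], sigma = sg, metric = metric,
                measurement = ms, baseline = bv, perturbed = pv,
                pct_change = pct)
            }
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Degeneracy summary of the valid networks
#'
#' Histograms of each synaptic weight over the valid networks plus the 8x8
#' pairwise Pearson correlation matrix and the list of its 28 unique
#' off-diagonal coefficients. Zero-variance weights yield NA (undefined)
#' correlations.
#'
#' @param search a \code{dg_network_search} with at least 3 valid networks.
#' @param breaks histogram breaks specification.
#' @return list with \code{histograms}, \code{weight_cor} (8x8) and
#'   \code{pairs} (data.frame with 28 rows: w1, w2, r).
#' @export
summarize_degeneracy <- function(search, breaks = "Sturges") {
  stopifnot(inherits(search, "dg_network_search"))
  W <- search$weights[search$valid, , drop = FALSE]
  if (nrow(W) < 3) stop("need at least 3 valid networks")
  hists <- lapply(as.data.frame(W), function(v)
    graphics::hist(v, breaks = breaks, plot = FALSE))
  C <- cor_undef_safe(W)
  idx <- which(upper.tri(C), arr.ind = TRUE)
  pairs <- data.frame(w1 = colnames(C)[idx[, 1]],
                      w2 = colnames(C)[idx[, 2]],
                      r = C[upper.tri(C)])
  list(histograms = hists, weight_cor = C, pairs = pairs)
}
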