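# Cellular-scale stochastic search (multi-parametric multi-objective
# stochastic search, MPMOSS): parameters are drawn uniformly and
# independently from per-subtype ranges, each candidate model is
# characterized with the six electrophysiological protocols, and models with
# every measurement inside its physiological range form the validated
# heterogeneous population for that subtype.

#' Sample aEIF parameters uniformly from per-parameter ranges
#'
#' Nine parameters are sampled per subtype; parameters absent from the range
#' list (by default the specific capacitance \code{C_m}) are held at the
#' subtype default.
#'
#' @param ranges named list of \code{c(min, max)} per sampled parameter
#'   (see \code{\link{dg_config}}'s \code{neuron_ranges}).
#' @param n number of draws.
#' @param seed integer seed.
#' @param subtype subtype label stamped on the rows.
#' @param defaults one-row table providing values for unsampled parameters.
#' @return data.frame of \code{n} parameter rows.
#' @export
sample_neuron_parameters <- function(ranges, n, seed = NULL, subtype = "GC",
                                     defaults = default_neuron_params()[[subtype]]) {
  stopifnot(n >= 1)
  if (length(ranges) == 0) stop("empty range list")
  bad <- vapply(ranges, function(r) r[1] > r[2], logical(1))
  if (any(bad)) stop("invalid range (min > max) for: ",
                     paste(names(ranges)[bad], collapse = ", "))
  tab <- with_seed(seed, {
    cols <- lapply(ranges, function(r) stats::runif(n, r[1], r[2]))
    as.data.frame(cols)
  })
  for (nm in setdiff(PARAM_NAMES, names(tab))) tab[[nm]] <- defaults[[nm]]
  tab$subtype <- subtype
  tab[, c("subtype", PARAM_NAMES)]
}

#' Run the cellular stochastic search for one subtype
#'
#' Samples \code{n} candidate models, measures all six electrophysiological
#' properties for each, validates against the subtype bounds, and returns
#' the full provenance-stamped result.
#'
#' @param ranges per-parameter sampling ranges for the subtype.
#' @param bounds measurement bounds table (all four subtypes; see
#'   \code{\link{dg_config}}).
#' @param n number of candidate models.
#' @param seed integer seed.
#' @param subtype one of GC, BC, MC, HC.
#' @param config \code{\link{dg_config}} (engine settings).
#' @return object of class \code{dg_cell_search}: list with \code{params}
#'   (sampled table), \code{measurements}, \code{valid} (logical vector),
#'   \code{N}, \code{N_valid}, \code{subtype}, \code{seed},
#'   \code{config_hash}.
#' @export
run_cell_mpmoss <- function(ranges, bounds, n, seed = NULL, subtype = "GC",
                            config = dg_config()) {
  subtype <- match.arg(subtype, SUBTYPES)
  eng <- engine_config(dt = config$engine$dt,
                       refractory = config$engine$refractory,
                       exp_cap = config$engine$exp_cap,
                       settle = config$engine$settle)
  params <- sample_neuron_parameters(ranges, n, seed = seed,
                                     subtype = subtype)
  meas <- vector("list", n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    m <- measure_ephys(params[i, , drop = FALSE], eng)
    meas[[i]] <- m
    valid[i] <- validate_neuron(m, bounds, subtype)$valid
  }
  structure(list(params = params, measurements = do.call(rbind, meas),
                 valid = valid, N = n, N_valid = sum(valid),
                 subtype = subtype, seed = seed,
                 config_hash = config_hash(config)),
            class = "dg_cell_search")
}

#' @export
print.dg_cell_search <- function(x, ...) {
  cat(sprintf("dg_cell_search (%s): %d / %d models valid (%.1f%%)\n",
              x$subtype, x$N_valid, x$N, 100 * x$N_valid / x$N))
  invisible(x)
}

#' Valid parameter rows of a search result
#'
#' @param result a \code{dg_cell_search}.
#' @return data.frame of the valid models' parameters.
#' @export
valid_models <- function(result) {
  stopifnot(inherits(result, "dg_cell_search"))
  result$params[result$valid, , drop = FALSE]
}

#' Generate validated populations for all four subtypes
#'
#' Convenience wrapper running one independent search per subtype (each on
#' its own child seed derived from the master seed).
#'
#' @param config \code{\link{dg_config}}.
#' @param n named or single count of candidates per subtype.
#' @param seed master seed.
#' @return named list of \code{dg_cell_search} results.
#' @export
search_all_subtypes <- function(config = dg_config(), n = 1000, seed = 1) {
  if (length(n) == 1) n <- stats::setNames(rep(n, 4), SUBTYPES)
  res <- lapply(seq_along(SUBTYPES), function(k) {
    st <- SUBTYPES[k]
    run_cell_mpmoss(config$neuron_ranges[[st]], config$ephys_bounds,
                    n[[st]], seed = child_seed(seed, k), subtype = st,
                    config = config)
  })
  stats::setNames(res, SUBTYPES)
}

# Pearson correlation matrix with zero-variance columns marked NA (no
# NaN propagation, no warnings).
cor_undef_safe <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  C <- suppressWarnings(stats::cor(X))
  C[sds == 0, ] <- NA_real_
  C[, sds == 0] <- NA_real_
  diag(C)[sds == 0] <- NA_real_
  C
}

#' Summaries of a validated population
#'
#' Per-parameter histograms plus pairwise Pearson correlation matrices of
#' the valid models' parameters and measurements. Zero-variance columns get
#' NA (undefined) correlations rather than NaN.
#'
#' @param result a \code{dg_cell_search} with at least 3 valid models.
#' @param breaks histogram breaks specification (as in
#'   \code{\link[graphics]{hist}}).
#' @return list with \code{histograms} (named list of \code{hist} objects),
#'   \code{param_cor} and \code{measurement_cor}.
#' @export
population_summary <- function(result, breaks = "Sturges") {
  stopifnot(inherits(result, "dg_cell_search"))
  if (result$N_valid < 3) stop("need at least 3 valid models")
  vp <- valid_models(result)
  num <- vp[, setdiff(names(vp), "subtype")]
  hists <- lapply(num, function(v)
    graphics::hist(v, breaks = breaks, plot = FALSE))
  vm <- result$measurements[result$valid, , drop = FALSE]
  vm <- vm[, colSums(!is.na(vm)) == nrow(vm), drop = FALSE]
  list(histograms = hists, param_cor = cor_undef_safe(num),
       measurement_cor = cor_undef_safe(vm))
}
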