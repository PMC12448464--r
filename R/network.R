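# Dentate gyrus network construction and structural perturbations.
#
# A network holds: the four cell populations with per-neuron aEIF parameters
# drawn without replacement from validated model pools (heterogeneous) or
# replicated from one base model per subtype (homogeneous); per-projection
# edge lists realized as independent Bernoulli draws with per-projection
# connection probabilities; and the eight per-projection synaptic weights.

NET_POPS <- c("GC", "BC", "MC", "HC")

#' Build a dentate gyrus network
#'
#' @param populations named list (\code{GC}, \code{BC}, \code{MC},
#'   \code{HC}) of parameter tables (rows = candidate neuron models, columns
#'   as in \code{\link{neuron_params}}). Each must contain at least as many
#'   rows as the corresponding population size; neurons are drawn without
#'   replacement so no model repeats within a subtype.
#' @param config a \code{\link{dg_config}}; supplies population sizes, the
#'   number of PP afferents, the synapse table and connection probabilities.
#' @param weights named numeric vector of the 8 per-projection peak
#'   conductances (nS); defaults to the hand-tuned config weights.
#' @param seed integer seed governing neuron selection and wiring.
#' @return object of class \code{dg_network}: list with \code{sizes},
#'   \code{n_pp}, \code{params} (list of per-neuron parameter tables),
#'   \code{edges} (per projection, list with 1-based \code{pre}, \code{post}
#'   index vectors), \code{synapses} (kinetics table), \code{weights} (nS),
#'   \code{seed} and \code{config_hash}.
#' @export
build_network <- function(populations, config = dg_config(), weights = NULL,
                          seed = NULL) {
  syn <- config$synapses
  sizes <- config$populations
  if (is.null(weights)) {
    weights <- stats::setNames(syn$gbar, syn$projection)
  }
  stopifnot(all(syn$projection %in% names(weights)))
  if (any(weights < 0)) stop("weights must be non-negative")
  params <- list()
  with_seed(seed, {
    for (pop in NET_POPS) {
      pool <- populations[[pop]]
      n <- sizes[[pop]]
      if (is.null(pool) || nrow(pool) < n)
        stop(sprintf("not enough valid %s models: need %d, have %d",
                     pop, n, if (is.null(pool)) 0L else nrow(pool)))
      pick <- sample.int(nrow(pool), n)  # without replacement
      params[[pop]] <- pool[pick, , drop = FALSE]
      rownames(params[[pop]]) <- NULL
    }
    wiring <- if (is.null(config$wiring)) "fixed_in" else config$wiring
    edges <- list()
    for (i in seq_len(nrow(syn))) {
      n_pre <- if (syn$pre[i] == "PP") config$input$n_trains
               else sizes[[syn$pre[i]]]
      n_post <- sizes[[syn$post[i]]]
      edges[[syn$projection[i]]] <- sample_edges(n_pre, n_post, syn$prob[i],
                                                 wiring)
    }
    structure(list(sizes = sizes, n_pp = config$input$n_trains,
                   params = params, edges = edges, synapses = syn,
                   weights = weights[syn$projection], seed = seed,
                   config_hash = config_hash(config),
                   heterogeneous = TRUE),
              class = "dg_network")
  })
}

# Random wiring of one projection at connection probability p.
#
# "fixed_in" (default): every postsynaptic neuron draws exactly
# round(p * n_pre) presynaptic partners uniformly without replacement, so
# in-degrees are equal and the afferent sampling is the only random element.
# "bernoulli": every potential pre x post pair is realized independently
# with probability p, which additionally spreads in-degrees binomially --
# that spread acts as a fixed multiplicative gain profile across the
# population and is pattern-unspecific, so the fixed-in-degree scheme is
# the default for pattern-separation studies.
sample_edges <- function(n_pre, n_post, p, wiring = "fixed_in") {
  if (p <= 0) return(list(pre = integer(0), post = integer(0)))
  if (p >= 1) {
    g <- expand.grid(pre = seq_len(n_pre), post = seq_len(n_post))
    return(list(pre = g$pre, post = g$post))
  }
  if (wiring == "bernoulli") {
    n_pairs <- n_pre * n_post
    hit <- which(stats::runif(n_pairs) < p)
    return(list(pre = as.integer((hit - 1) %% n_pre + 1),
                post = as.integer((hit - 1) %/% n_pre + 1)))
  }
  k <- max(1L, round_half_up(p * n_pre))
  pre <- unlist(lapply(seq_len(n_post), function(j) sample.int(n_pre, k)))
  list(pre = as.integer(pre), post = rep(seq_len(n_post), each = k))
}

#' @export
print.dg_network <- function(x, ...) {
  cat("dg_network:", paste(names(x$sizes), x$sizes, sep = "=",
                           collapse = ", "),
      "+", x$n_pp, "PP afferents\n")
  cat("  ", if (x$heterogeneous) "heterogeneous" else "homogeneous",
      "neuron assignment\n")
  ne <- vapply(x$edges, function(e) length(e$pre), integer(1))
  cat("  edges:", paste(names(ne), ne, sep = "=", collapse = ", "), "\n")
  cat("  weights (nS):", paste(names(x$weights),
                               signif(x$weights, 3), sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

#' Delete an interneuron subtype
#'
#' Functional deletion: sets the weights of every projection onto or from
#' the subtype to zero, leaving the rest of the network untouched.
#'
#' @param net a \code{dg_network}.
#' @param subtype one of \code{"BC"}, \code{"MC"}, \code{"HC"}.
#' @return the modified network.
#' @export
delete_subtype <- function(net, subtype) {
  subtype <- match.arg(subtype, c("BC", "MC", "HC"))
  hit <- net$synapses$pre == subtype | net$synapses$post == subtype
  net$weights[hit] <- 0
  net
}

#' Jitter synaptic weights
#'
#' Perturbs each of the eight projection weights with an independent
#' zero-mean Gaussian draw of standard deviation \code{sigma * scale *
#' weight} (relative units: one sigma level perturbs each weight by
#' \code{scale} of its own magnitude). Perturbed weights are floored at zero
#' since a conductance cannot be negative.
#'
#' @param net a \code{dg_network}.
#' @param sigma jitter level (the experiments use 1, 3, 5).
#' @param seed integer seed.
#' @param scale relative SD per sigma unit (default from the perturbation
#'   settings of \code{\link{dg_config}}).
#' @return the perturbed network.
#' @export
jitter_weights <- function(net, sigma, seed = NULL, scale = 0.02) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(net)
  with_seed(seed, {
    jit <- stats::rnorm(length(net$weights), 0, sigma * scale * abs(net$weights))
    net$weights <- pmax(net$weights + jit, 0)
    net
  })
}

#' Replace heterogeneous neurons by one base model per subtype
#'
#' Every neuron of a subtype receives the same base parameter set;
#' adjacency, weights and all other properties are conserved, producing the
#' homogeneous counterpart of a heterogeneous network.
#'
#' @param net a \code{dg_network}.
#' @param base_models named list of one-row parameter tables per subtype
#'   (default: the hand-tuned subtype defaults of \code{\link{dg_config}}).
#' @return the homogenized network.
#' @export
make_homogeneous <- function(net, base_models = default_neuron_params()) {
  for (pop in NET_POPS) {
    base <- base_models[[pop]]
    stopifnot(nrow(base) == 1)
    net$params[[pop]] <- base[rep(1, net$sizes[[pop]]), , drop = FALSE]
    rownames(net$params[[pop]]) <- NULL
  }
  net$heterogeneous <- FALSE
  net
}

#' Export edge lists as a data.frame
#'
#' @param net a \code{dg_network}.
#' @return data.frame with \code{projection}, \code{pre}, \code{post}.
#' @export
network_edge_table <- function(net) {
  do.call(rbind, lapply(names(net$edges), function(pj) {
    e <- net$edges[[pj]]
    if (length(e$pre) == 0) return(NULL)
    data.frame(projection = pj, pre = e$pre, post = e$post,
               stringsAsFactors = FALSE)
  }))
}
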