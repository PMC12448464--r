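# Perforant-path input patterns.
#
# An input pattern is a set of independent spike trains. Base patterns are
# homogeneous Poisson processes (inter-spike intervals drawn from an
# exponential distribution and accumulated until the duration is exceeded);
# at the default 8 Hz the mean ISI is 125 ms. Pairs of independent base
# patterns are progressively morphed into one another by swapping a beta
# fraction of the trains, yielding families of patterns with graded
# similarity.

#' Generate a base spike pattern
#'
#' @param n_trains number of independent spike trains.
#' @param rate_hz mean firing rate per train (Hz).
#' @param duration_ms pattern duration (ms); spikes lie in
#'   \code{[0, duration_ms)}.
#' @param seed integer seed (optional, for reproducibility).
#' @param rate_distribution form of the across-train firing-rate
#'   distribution. \code{"poisson"} (default): each train's rate is drawn
#'   from a Poisson distribution with mean \code{rate_hz}, so the population
#'   rate map has Poisson-distributed structure around the mean;
#'   \code{"exponential"}: per-train rates are drawn from an exponential
#'   distribution with the same mean, giving a heavier-tailed rate map. In
#'   both cases each train is then a homogeneous Poisson process at its own
#'   rate (inter-spike intervals exponential with mean \code{1000/rate} ms).
#' @return An object of class \code{spike_pattern}: list with \code{trains}
#'   (list of strictly increasing spike-time vectors, ms), \code{n_trains},
#'   \code{duration}, \code{rate_hz}, \code{beta} (morph coordinate, 0 for a
#'   base pattern) and \code{seed}.
#' @export
generate_base_pattern <- function(n_trains, rate_hz, duration_ms, seed = NULL,
                                  rate_distribution = c("poisson", "exponential")) {
  stopifnot(n_trains >= 1, rate_hz > 0, duration_ms >= 0)
  rate_distribution <- match.arg(rate_distribution)
  trains <- with_seed(seed, {
    rates <- if (rate_distribution == "poisson")
      stats::rpois(n_trains, rate_hz)
    else stats::rexp(n_trains, 1 / rate_hz)
    lapply(rates, function(r) poisson_train(r, duration_ms))
  })
  structure(list(trains = trains, n_trains = as.integer(n_trains),
                 duration = duration_ms, rate_hz = rate_hz, beta = 0,
                 seed = seed, rate_distribution = rate_distribution),
            class = "spike_pattern")
}

# draw exponential ISIs (mean 1000/rate ms) and accumulate
poisson_train <- function(rate_hz, duration_ms) {
  if (duration_ms <= 0 || rate_hz <= 0) return(numeric(0))
  mean_isi <- 1000 / rate_hz
  n_guess <- max(10, ceiling(duration_ms / mean_isi * 1.5 + 5 * sqrt(duration_ms / mean_isi)))
  t <- cumsum(stats::rexp(n_guess, 1 / mean_isi))
  while (t[length(t)] < duration_ms)
    t <- c(t, t[length(t)] + cumsum(stats::rexp(n_guess, 1 / mean_isi)))
  t[t < duration_ms]
}

#' @export
print.spike_pattern <- function(x, ...) {
  n_sp <- sum(lengths(x$trains))
  cat(sprintf("spike_pattern: %d trains, %.0f ms, beta = %g, %d spikes (%.2f Hz mean)\n",
              x$n_trains, x$duration, x$beta, n_sp,
              1000 * n_sp / (x$n_trains * x$duration)))
  invisible(x)
}

#' Morph between two base patterns
#'
#' For each morph level beta, \code{round(beta * n_trains)} train indices
#' take their spike train from \code{P1} and the rest from \code{P0}
#' (rounding half away from zero). Selection is nested across beta by
#' default: a single random permutation of train indices is drawn and
#' \code{P_beta} replaces its first \code{round(beta * n)} entries, so the
#' replaced set grows monotonically and the patterns morph progressively.
#' Independent per-beta selection is available with \code{nested = FALSE}.
#'
#' @param P0,P1 \code{spike_pattern}s with identical \code{n_trains} and
#'   \code{duration}.
#' @param betas morph levels in \code{[0, 1]}; the default 0, 0.1, ..., 1
#'   yields 11 patterns.
#' @param seed integer seed for the train selection.
#' @param nested logical, see above.
#' @return A list of \code{spike_pattern}s, one per beta, each carrying a
#'   logical attribute-like field \code{from_P1} marking replaced trains.
#' @export
morph_patterns <- function(P0, P1, betas = seq(0, 1, 0.1), seed = NULL,
                           nested = TRUE) {
  stopifnot(inherits(P0, "spike_pattern"), inherits(P1, "spike_pattern"))
  if (P0$n_trains != P1$n_trains || P0$duration != P1$duration)
    stop("P0 and P1 must have the same number of trains and duration")
  if (any(betas < 0 | betas > 1)) stop("betas must lie in [0, 1]")
  n <- P0$n_trains
  with_seed(seed, {
    perm <- sample.int(n)
    lapply(betas, function(beta) {
      k <- round_half_up(beta * n)
      take <- if (nested) perm[seq_len(k)] else sample.int(n, k)
      from_P1 <- logical(n)
      from_P1[take] <- TRUE
      trains <- P0$trains
      trains[take] <- P1$trains[take]
      structure(list(trains = trains, n_trains = n, duration = P0$duration,
                     rate_hz = P0$rate_hz, beta = beta, seed = seed,
                     from_P1 = from_P1),
                class = "spike_pattern")
    })
  })
}

round_half_up <- function(x) floor(x + 0.5)

#' Generate a morphed input-pattern set
#'
#' Draws two independent base patterns, checks that they are effectively
#' uncorrelated (|Pearson r| between their rate vectors below
#' \code{distinctness_r}, regenerating \code{P1} with a fresh seed
#' otherwise), and morphs between them.
#'
#' @inheritParams generate_base_pattern
#' @param betas morph levels.
#' @param distinctness_r distinctness threshold on the base-pattern rate
#'   correlation.
#' @param max_tries regeneration attempts before giving up.
#' @return list with \code{patterns} (list of \code{spike_pattern}, one per
#'   beta), \code{betas}, \code{P0}, \code{P1} and the \code{r01} actually
#'   achieved.
#' @export
make_pattern_set <- function(n_trains, rate_hz, duration_ms, seed = NULL,
                             betas = seq(0, 1, 0.1),
                             rate_distribution = "poisson",
                             distinctness_r = 0.1, max_tries = 20) {
  P0 <- generate_base_pattern(n_trains, rate_hz, duration_ms,
                              seed = child_seed(seed, 1),
                              rate_distribution = rate_distribution)
  r01 <- Inf
  for (k in seq_len(max_tries)) {
    P1 <- generate_base_pattern(n_trains, rate_hz, duration_ms,
                                seed = child_seed(seed, 1 + k),
                                rate_distribution = rate_distribution)
    r01 <- stats::cor(pattern_rate_map(P0), pattern_rate_map(P1))
    if (is.na(r01) || abs(r01) < distinctness_r) break
  }
  if (!is.na(r01) && abs(r01) >= distinctness_r)
    stop("could not generate sufficiently distinct base patterns")
  patterns <- morph_patterns(P0, P1, betas, seed = child_seed(seed, 101))
  list(patterns = patterns, betas = betas, P0 = P0, P1 = P1, r01 = r01)
}

#' Per-train average firing rates
#'
#' @param P a \code{spike_pattern}.
#' @param window \code{c(start, end)} in ms within \code{[0, duration]};
#'   defaults to the full pattern.
#' @return numeric vector of rates (Hz), one per train.
#' @export
pattern_rate_map <- function(P, window = c(0, P$duration)) {
  stopifnot(length(window) == 2)
  if (diff(window) <= 0) stop("window must have positive length")
  if (window[1] < 0 || window[2] > P$duration)
    stop("window must lie within [0, duration]")
  counts <- vapply(P$trains, function(tr)
    sum(tr >= window[1] & tr < window[2]), numeric(1))
  counts / (diff(window) / 1000)
}

#' Pooled inter-spike intervals of a pattern
#'
#' @param P a \code{spike_pattern}.
#' @return numeric vector of within-train ISIs (ms) pooled over trains.
#' @export
pattern_isis <- function(P) {
  unlist(lapply(P$trains, diff), use.names = FALSE)
}
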