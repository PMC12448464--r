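# Similarity metrics between activity patterns.
#
# Patterns are compared through their per-neuron firing rates (Hamming
# distance, normalized Euclidean distance, cosine similarity, mutual
# information, Pearson correlation of average rates r) or through the
# pairwise-correlation structure of Gaussian-smoothed instantaneous rates
# (R). For the distance metrics the rate vectors are normalized by the
# maximum rate over the two compared patterns; the correlation-based metrics
# are invariant to this scaling.

metric_ids <- function() c("HD", "nED", "cosine", "MI", "r", "R")

# shared-max normalization used by the distance metrics
normalize_rates <- function(F0, Fb) {
  mx <- max(F0, Fb)
  if (mx <= 0) return(list(F0 = F0, Fb = Fb))
  list(F0 = F0 / mx, Fb = Fb / mx)
}

check_lengths <- function(F0, Fb) {
  if (length(F0) != length(Fb)) stop("rate vectors must have equal length")
}

#' Hamming distance between rate vectors
#'
#' Sum of absolute differences of the normalized rates.
#' @param F0,Fb per-neuron average firing rates (Hz) of the two patterns.
#' @param normalize divide both vectors by their shared maximum first.
#' @return non-negative scalar.
#' @export
hamming_distance <- function(F0, Fb, normalize = TRUE) {
  check_lengths(F0, Fb)
  if (normalize) {
    n <- normalize_rates(F0, Fb); F0 <- n$F0; Fb <- n$Fb
  }
  sum(abs(F0 - Fb))
}

#' Normalized Euclidean distance between rate vectors
#'
#' \code{sqrt(sum((F0 - Fb)^2) / N)} on the normalized rates.
#' @inheritParams hamming_distance
#' @return non-negative scalar.
#' @export
normalized_euclidean <- function(F0, Fb, normalize = TRUE) {
  check_lengths(F0, Fb)
  if (normalize) {
    n <- normalize_rates(F0, Fb); F0 <- n$F0; Fb <- n$Fb
  }
  sqrt(sum((F0 - Fb)^2) / length(F0))
}

#' Cosine similarity between rate vectors
#'
#' @inheritParams hamming_distance
#' @return scalar in [-1, 1]; \code{NA} if either vector is all-zero.
#' @export
cosine_similarity <- function(F0, Fb) {
  check_lengths(F0, Fb)
  n0 <- sqrt(sum(F0^2)); nb <- sqrt(sum(Fb^2))
  if (n0 == 0 || nb == 0) return(NA_real_)
  sum(F0 * Fb) / (n0 * nb)
}

#' Mutual information between binned rate vectors
#'
#' Plug-in estimate (log base 2) from the joint histogram of the two rate
#' vectors discretized into equal-width bins spanning their pooled range.
#'
#' @inheritParams hamming_distance
#' @param bins number of equal-width bins.
#' @return MI in bits (0 if either margin occupies a single bin).
#' @export
mutual_information <- function(F0, Fb, bins = 10) {
  check_lengths(F0, Fb)
  rng <- range(c(F0, Fb))
  if (diff(rng) == 0) return(0)
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  i0 <- findInterval(F0, brk, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(Fb, brk, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(factor(i0, levels = 1:bins), factor(ib, levels = 1:bins))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Pearson correlation of average firing rates
#'
#' @inheritParams hamming_distance
#' @return correlation in [-1, 1]; \code{NA} if either vector has zero
#'   variance.
#' @export
rate_correlation <- function(F0, Fb) {
  check_lengths(F0, Fb)
  if (stats::sd(F0) == 0 || stats::sd(Fb) == 0) return(NA_real_)
  stats::cor(F0, Fb)
}

#' Gaussian-smoothed instantaneous firing rates
#'
#' Convolves each spike train with a Gaussian kernel whose SD is
#' \code{1 / (10 f)} seconds, where \code{f} is that train's average rate in
#' the window; the kernel is truncated at four SDs. Trains with no spikes
#' map to the zero function.
#'
#' @param trains list of spike-time vectors (ms).
#' @param window analysis window \code{c(start, end)} (ms).
#' @param rate_dt sampling step of the rate series (ms).
#' @return matrix (time points x trains) of smoothed rates (arbitrary
#'   scaling; only correlations are used downstream).
#' @export
smooth_rates <- function(trains, window, rate_dt = 1) {
  t0 <- window[1]; t1 <- window[2]
  n_t <- round((t1 - t0) / rate_dt)
  grid_n <- n_t
  M <- matrix(0, grid_n, length(trains))
  win_s <- (t1 - t0) / 1000
  for (i in seq_along(trains)) {
    sp <- trains[[i]]
    sp <- sp[sp >= t0 & sp < t1]
    if (length(sp) == 0) next
    f <- length(sp) / win_s                 # Hz
    sigma_ms <- 1000 / (10 * f)             # 1/(10 f) seconds
    half <- max(1L, ceiling(4 * sigma_ms / rate_dt))
    kern <- stats::dnorm(seq(-half, half) * rate_dt, sd = sigma_ms)
    idx <- floor((sp - t0) / rate_dt) + 1
    v <- numeric(grid_n + 2 * half)
    for (j in idx) {
      rng <- j:(j + 2 * half)
      v[rng] <- v[rng] + kern
    }
    M[, i] <- v[(half + 1):(half + grid_n)]
  }
  M
}

# Pairwise Pearson matrix with zero-variance columns treated as correlation
# 0 against everything (their rows/columns are zeroed; diagonal kept at 1
# only for non-constant series).
pairwise_pearson <- function(M) {
  sds <- apply(M, 2, stats::sd)
  Z <- scale(M)
  Z[, sds == 0] <- 0
  C <- crossprod(Z) / (nrow(M) - 1)
  diag(C) <- ifelse(sds == 0, 0, 1)
  C
}

#' Correlation of instantaneous-rate correlation structure
#'
#' For each pattern, computes the matrix of pairwise Pearson correlations
#' between the Gaussian-smoothed instantaneous rates of all trains, then
#' correlates the upper triangles (diagonal excluded) of the two matrices.
#'
#' @param trains0,trainsb lists of spike-time vectors (ms), equal length N.
#' @param window analysis window (ms).
#' @param rate_dt sampling step of the smoothed rate series (ms).
#' @return Pearson correlation of the two correlation structures;
#'   \code{NA} if N < 3 or either triangle is constant.
#' @export
instantaneous_rate_correlation <- function(trains0, trainsb, window,
                                           rate_dt = 1) {
  if (length(trains0) != length(trainsb))
    stop("patterns must have the same number of trains")
  if (length(trains0) < 3) return(NA_real_)
  C0 <- pairwise_pearson(smooth_rates(trains0, window, rate_dt))
  Cb <- pairwise_pearson(smooth_rates(trainsb, window, rate_dt))
  ut <- upper.tri(C0)
  a <- C0[ut]; b <- Cb[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Compute one similarity metric between two patterns
#'
#' Dispatcher used by the metric-vs-beta machinery.
#'
#' @param metric one of \code{"HD"}, \code{"nED"}, \code{"cosine"},
#'   \code{"MI"}, \code{"r"}, \code{"R"}.
#' @param P0,Pb \code{spike_pattern}s.
#' @param window analysis window (ms); default full pattern.
#' @param bins histogram bins for \code{"MI"}.
#' @param rate_dt rate-series sampling step (ms) for \code{"R"}.
#' @return scalar metric value.
#' @export
pattern_similarity <- function(metric, P0, Pb, window = c(0, P0$duration),
                               bins = 10, rate_dt = 1) {
  metric <- match.arg(metric, metric_ids())
  if (metric == "R")
    return(instantaneous_rate_correlation(P0$trains, Pb$trains, window,
                                          rate_dt))
  F0 <- pattern_rate_map(P0, window)
  Fb <- pattern_rate_map(Pb, window)
  switch(metric,
         HD = hamming_distance(F0, Fb),
         nED = normalized_euclidean(F0, Fb),
         cosine = cosine_similarity(F0, Fb),
         MI = mutual_information(F0, Fb, bins),
         r = rate_correlation(F0, Fb))
}

#' Metric-versus-beta curve for a morphed pattern set
#'
#' @param patterns list of \code{spike_pattern}s (from
#'   \code{\link{morph_patterns}} or \code{\link{make_pattern_set}}); the
#'   first is the reference P0.
#' @param metric metric id, see \code{\link{pattern_similarity}}.
#' @param window analysis window (ms).
#' @param bins histogram bins for \code{"MI"}.
#' @param rate_dt rate-series sampling step (ms) for \code{"R"}.
#' @return data.frame with \code{beta}, \code{metric}, \code{value}.
#' @export
similarity_vs_beta <- function(patterns, metric, window = NULL, bins = 10,
                               rate_dt = 1) {
  P0 <- patterns[[1]]
  if (is.null(window)) window <- c(0, P0$duration)
  vals <- vapply(patterns, function(P)
    pattern_similarity(metric, P0, P, window, bins, rate_dt), numeric(1))
  data.frame(beta = vapply(patterns, function(P) P$beta, numeric(1)),
             metric = metric, value = vals, stringsAsFactors = FALSE)
}

#' Invariance harness for similarity metrics
#'
#' Reproduces the metric-selection analysis: for one experimental factor
#' (population size, mean rate, or rate-distribution form), generates
#' \code{n_sets} independent morphed pattern families per factor setting,
#' computes metric-versus-beta curves, and averages them across sets. A
#' usable input/output similarity metric should produce curves that coincide
#' across settings (invariance); the distance metrics do not.
#'
#' @param metrics character vector of metric ids.
#' @param factor one of \code{"size"}, \code{"rate"}, \code{"distribution"}.
#' @param settings factor levels; defaults: sizes 1000/2000/3000, rates
#'   5/15/25 Hz, distributions poisson/exponential.
#' @param n_sets independent pattern families per setting.
#' @param seed master seed.
#' @param n_trains,rate_hz,duration_ms pattern parameters for the factors not
#'   being varied.
#' @param betas morph levels.
#' @param rate_dt sampling step (ms) for the instantaneous-rate metric.
#' @return data.frame with \code{factor}, \code{setting}, \code{metric},
#'   \code{beta}, \code{value} (mean over sets).
#' @export
invariance_harness <- function(metrics = c("r", "R", "HD", "nED"),
                               factor = c("size", "rate", "distribution"),
                               settings = NULL, n_sets = 10, seed = 1,
                               n_trains = 700, rate_hz = 8,
                               duration_ms = 2000,
                               betas = seq(0, 1, 0.1), rate_dt = 5) {
  factor <- match.arg(factor)
  if (is.null(settings))
    settings <- switch(factor,
                       size = c(1000, 2000, 3000),
                       rate = c(5, 15, 25),
                       distribution = c("poisson", "exponential"))
  out <- list()
  for (si in seq_along(settings)) {
    s <- settings[[si]]
    n <- if (factor == "size") as.integer(s) else n_trains
    rt <- if (factor == "rate") as.numeric(s) else rate_hz
    dist <- if (factor == "distribution") as.character(s) else "poisson"
    acc <- NULL
    for (k in seq_len(n_sets)) {
      ps <- make_pattern_set(n, rt, duration_ms,
                             seed = child_seed(seed, si * 1000 + k),
                             betas = betas, rate_distribution = dist)
      curves <- do.call(rbind, lapply(metrics, function(m)
        similarity_vs_beta(ps$patterns, m, rate_dt = rate_dt)))
      acc <- if (is.null(acc)) curves else {
        acc$value <- acc$value + curves$value
        acc
      }
    }
    acc$value <- acc$value / n_sets
    acc$factor <- factor
    acc$setting <- as.character(s)
    out[[si]] <- acc
  }
  res <- do.call(rbind, out)
  res[, c("factor", "setting", "metric", "beta", "value")]
}
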