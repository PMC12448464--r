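# Similarity metrics: closed-form cases, independent oracles, and the
# instantaneous-rate correlation pipeline.

test_that("Hamming distance matches its definition", {
  expect_equal(hamming_distance(c(1, 0, 1), c(1, 1, 1), normalize = FALSE), 1)
  expect_equal(hamming_distance(1:5, 1:5), 0)
  set.seed(1)
  F0 <- runif(50, 0, 20); Fb <- runif(50, 0, 20)
  mx <- max(F0, Fb)
  expect_equal(hamming_distance(F0, Fb), sum(abs(F0 / mx - Fb / mx)))
  expect_error(hamming_distance(1:3, 1:4), "equal length")
})

test_that("normalized Euclidean distance matches its definition", {
  expect_equal(normalized_euclidean(c(1, 0), c(0, 1), normalize = FALSE), 1)
  expect_equal(normalized_euclidean(1:4, 1:4), 0)
  set.seed(2)
  F0 <- runif(30, 0, 10); Fb <- runif(30, 0, 10)
  mx <- max(F0, Fb)
  expect_equal(normalized_euclidean(F0, Fb),
               sqrt(sum((F0 / mx - Fb / mx)^2) / 30))
})

test_that("cosine similarity handles identical, orthogonal and zero vectors", {
  expect_equal(cosine_similarity(c(2, 3, 1), c(2, 3, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0, 2, 0), c(0, 3, 0, 4)), 0)
  expect_true(is.na(cosine_similarity(c(0, 0), c(1, 2))))
  set.seed(3)
  F0 <- runif(40); Fb <- runif(40)
  expect_equal(cosine_similarity(F0, Fb),
               sum(F0 * Fb) / sqrt(sum(F0^2) * sum(Fb^2)))
})

test_that("mutual information reproduces textbook cases", {
  # identical vectors: MI equals the marginal entropy of the binned rates
  F0 <- c(rep(1, 25), rep(10, 25), rep(20, 50))
  mi_self <- mutual_information(F0, F0, bins = 4)
  p <- table(findInterval(F0, seq(1, 20, length.out = 5),
                          rightmost.closed = TRUE, all.inside = TRUE)) / 100
  expect_equal(mi_self, -sum(p * log2(p)), tolerance = 1e-12)

  # diagonal 2x2 joint with probability 1/2 each: exactly 1 bit
  a <- rep(c(0, 10), each = 50)
  expect_equal(mutual_information(a, a, bins = 2), 1)

  # independent large samples: plug-in MI small
  set.seed(4)
  x <- runif(5000); y <- runif(5000)
  expect_lt(mutual_information(x, y, bins = 10), 0.02)

  # constant vectors occupy a single bin
  expect_equal(mutual_information(rep(3, 10), rep(3, 10)), 0)
})

test_that("average-rate correlation is Pearson with safe degenerate handling", {
  F0 <- c(1, 4, 2, 8)
  expect_equal(rate_correlation(F0, F0), 1)
  expect_equal(rate_correlation(F0, 3 * F0 + 2), 1)  # affine invariance
  expect_true(is.na(rate_correlation(F0, rep(2, 4))))
  set.seed(5)
  a <- rnorm(60); b <- rnorm(60)
  cov_ab <- sum((a - mean(a)) * (b - mean(b)))
  expect_equal(rate_correlation(a, b),
               cov_ab / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
})

test_that("instantaneous-rate correlation: identity, relabeling and a brute-force oracle", {
  set.seed(6)
  trains <- lapply(1:6, function(i) sort(runif(30, 0, 2000)))
  win <- c(0, 2000)
  expect_equal(instantaneous_rate_correlation(trains, trains, win), 1)

  # consistent relabeling of both patterns leaves the value unchanged
  trains_b <- lapply(1:6, function(i) sort(runif(25, 0, 2000)))
  perm <- c(3, 1, 2, 6, 4, 5)
  v1 <- instantaneous_rate_correlation(trains, trains_b, win)
  v2 <- instantaneous_rate_correlation(trains[perm], trains_b[perm], win)
  expect_equal(v1, v2, tolerance = 1e-10)

  # independent reimplementation of the full pipeline on a 4-train case
  tr0 <- list(c(100, 900, 1500), c(300, 1200), c(50, 700, 1300, 1900),
              c(400, 1600))
  trb <- list(c(150, 950), c(200, 800, 1700), c(600, 1250), c(450, 1450))
  rate_dt <- 1
  grid <- seq(0.5, 1999.5, rate_dt)
  smooth_one <- function(sp) {
    f <- length(sp) / 2                  # Hz over 2 s
    sigma <- 1000 / (10 * f)
    rowSums(vapply(sp, function(s) {
      v <- stats::dnorm(grid - s, sd = sigma)
      v[abs(grid - s) > 4 * sigma] <- 0
      v
    }, numeric(length(grid))))
  }
  cmat <- function(trs) stats::cor(vapply(trs, smooth_one,
                                          numeric(length(grid))))
  C0 <- cmat(tr0); Cb <- cmat(trb)
  oracle <- stats::cor(C0[upper.tri(C0)], Cb[upper.tri(Cb)])
  got <- instantaneous_rate_correlation(tr0, trb, win, rate_dt = 1)
  expect_equal(got, oracle, tolerance = 0.05)

  expect_true(is.na(instantaneous_rate_correlation(trains[1:2], trains_b[1:2],
                                                   win)))
})

test_that("zero-spike trains enter the correlation structure as zeros", {
  trains <- list(c(100, 500, 900), numeric(0), c(200, 1400), c(700, 1100))
  M <- smooth_rates(trains, c(0, 2000), rate_dt = 2)
  expect_true(all(M[, 2] == 0))
  C <- dgsep:::pairwise_pearson(M)
  expect_true(all(C[2, ] == 0))
  expect_equal(diag(C)[2], 0)
  expect_equal(diag(C)[1], 1)
})

test_that("metric-versus-beta curves behave at the self-comparison point", {
  ps <- make_pattern_set(150, 8, 1500, seed = 23)
  for (m in c("HD", "nED")) {
    curve <- similarity_vs_beta(ps$patterns, m)
    expect_equal(curve$value[1], 0)
    expect_gt(curve$value[11], curve$value[2])
  }
  for (m in c("cosine", "r")) {
    curve <- similarity_vs_beta(ps$patterns, m)
    expect_equal(curve$value[1], 1)
  }
})
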