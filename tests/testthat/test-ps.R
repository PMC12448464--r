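# Pattern-separation quantification: rotation, cubic fitting, analytic
# areas, transition point and the eight-check validator.

test_that("45-degree rotation maps the canonical points correctly", {
  expect_equal(rotate_points(1, 1), data.frame(x = sqrt(2), y = 0))
  r10 <- rotate_points(1, 0)
  expect_equal(r10$x, 1 / sqrt(2))
  expect_equal(r10$y, -1 / sqrt(2))  # separation side: below zero
  r01 <- rotate_points(0, 1)
  expect_equal(r01$y, +1 / sqrt(2))  # completion side
})

test_that("rotation is an isometry", {
  set.seed(7)
  s_in <- runif(10); s_out <- runif(10)
  rot <- rotate_points(s_in, s_out)
  d0 <- dist(cbind(s_in, s_out))
  d1 <- dist(cbind(rot$x, rot$y))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
})

test_that("cubic fitting recovers exact and least-squares solutions", {
  x <- seq(-1, 2, length.out = 9)
  y <- 0.3 - 0.5 * x + 0.2 * x^2 + 0.7 * x^3
  fit <- fit_cubic(x, y)
  expect_equal(fit$coef, c(0.3, -0.5, 0.2, 0.7), tolerance = 1e-9)
  expect_false(fit$degenerate)

  # noisy data against an explicit normal-equations oracle
  set.seed(8)
  yn <- y + rnorm(9, 0, 0.1)
  X <- outer(x, 0:3, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% yn)
  expect_equal(fit_cubic(x, yn)$coef, as.numeric(beta), tolerance = 1e-8)

  # constant data: higher coefficients vanish
  fc <- fit_cubic(x, rep(2, 9))
  expect_equal(fc$coef[2:4], rep(0, 3), tolerance = 1e-9)

  # duplicated abscissae force a flagged lower-degree fit
  fd <- fit_cubic(rep(c(0, 1), 5), rep(c(0, 1), 5))
  expect_true(fd$degenerate)
})

test_that("measurements on analytic test polynomials match closed forms", {
  # p(x) = x - 0.5 on [0, 1]: crossing is negative -> positive, so the
  # completion-to-separation transition is at the range start
  m <- ps_measurements(c(-0.5, 1, 0, 0), c(0, 1))
  expect_equal(m$A_PS, 0.125)
  expect_equal(m$A_PC, 0.125)
  expect_equal(m$PS_max, 0.5)
  expect_equal(m$T_PCPS, 0)

  # constant separation p(x) = -c on [0, L]
  m2 <- ps_measurements(c(-0.3, 0, 0, 0), c(0, 2))
  expect_equal(m2$A_PS, 0.6)
  expect_equal(m2$A_PC, 0)
  expect_equal(m2$PS_max, 0.3)
  expect_equal(m2$T_PCPS, 0)

  # positive-to-negative crossing lands at the root
  m3 <- ps_measurements(c(0.5, -1, 0, 0), c(0, 1))  # p = 0.5 - x
  expect_equal(m3$T_PCPS, 0.5)
  expect_equal(m3$A_PS, 0.125)
  expect_equal(m3$PS_max, 0.5)
})

test_that("areas agree with numerical quadrature on random cubics", {
  set.seed(9)
  for (k in 1:25) {
    cf <- rnorm(4, 0, c(0.3, 1, 1, 1))
    lo <- runif(1, -1, 0); hi <- runif(1, 0.5, 2)
    m <- ps_measurements(cf, c(lo, hi))
    xg <- seq(lo, hi, length.out = 20001)
    pg <- cf[1] + cf[2] * xg + cf[3] * xg^2 + cf[4] * xg^3
    h <- (hi - lo) / 20000
    aps <- sum(pmax(-pg, 0)) * h
    apc <- sum(pmax(pg, 0)) * h
    # absolute error bounds: the rectified areas can legitimately be ~0
    expect_lt(abs(m$A_PS - aps), 1e-3)
    expect_lt(abs(m$A_PC - apc), 1e-3)
    expect_lt(abs(m$PS_max - max(0, -min(pg))), 1e-4)
    # rectification consistency: A_PS - A_PC = -integral of p
    anti <- function(x) cf[1] * x + cf[2] * x^2 / 2 + cf[3] * x^3 / 3 +
      cf[4] * x^4 / 4
    expect_equal(m$A_PS - m$A_PC, -(anti(hi) - anti(lo)), tolerance = 1e-9)
  }
})

test_that("an identity network yields zero separation measurements", {
  s_in <- seq(0.1, 1, length.out = 11)
  res <- ps_from_curve(s_in, s_in)
  expect_equal(res$measurements$A_PS, 0, tolerance = 1e-9)
  expect_equal(res$measurements$A_PC, 0, tolerance = 1e-9)
  expect_equal(res$measurements$PS_max, 0, tolerance = 1e-6)
})

test_that("the validator is a strict conjunction over eight checks", {
  bounds <- list(A_PS_min = 0.15, A_PC_max = 0.02, T_PCPS_max = 0.25,
                 PS_max_min = 0.2)
  good <- list(A_PS = 0.3, A_PC = 0.001, T_PCPS = 0.1, PS_max = 0.35)
  expect_true(validate_network_ps(good, good, bounds)$valid)

  bad_apc <- good; bad_apc$A_PC <- 0.03
  expect_false(validate_network_ps(bad_apc, good, bounds)$valid)
  expect_false(validate_network_ps(good, bad_apc, bounds)$valid)

  # toggling each single bound flips the verdict exactly then
  viol <- list(A_PS = 0.1, A_PC = 0.05, T_PCPS = 0.4, PS_max = 0.1)
  for (nm in names(good)) {
    one_bad <- good
    one_bad[[nm]] <- viol[[nm]]
    v <- validate_network_ps(one_bad, good, bounds)
    expect_false(v$valid)
    expect_equal(sum(!v$checks), 1)
  }

  # undefined measurements fail
  expect_false(validate_network_ps(list(A_PS = NA, A_PC = 0, T_PCPS = 0,
                                        PS_max = 1), good, bounds)$valid)
})

test_that("relaxing any bound never shrinks the accepted set", {
  bounds <- list(A_PS_min = 0.15, A_PC_max = 0.02, T_PCPS_max = 0.25,
                 PS_max_min = 0.2)
  relaxed <- list(A_PS_min = 0.1, A_PC_max = 0.05, T_PCPS_max = 0.4,
                  PS_max_min = 0.1)
  set.seed(10)
  for (k in 1:40) {
    m <- list(A_PS = runif(1, 0, 0.5), A_PC = runif(1, 0, 0.1),
              T_PCPS = runif(1, 0, 0.6), PS_max = runif(1, 0, 0.5))
    if (validate_network_ps(m, m, bounds)$valid)
      expect_true(validate_network_ps(m, m, relaxed)$valid)
  }
})
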