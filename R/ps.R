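# Quantification of pattern separation from output-vs-input similarity.
#
# For each morph level the similarity among inputs (S_in) and among granule
# cell outputs (S_out) is one point of the S_out-vs-S_in curve. Points below
# the identity line are pattern separation, above it pattern completion.
# The points are rotated clockwise by 45 degrees so the identity line
# becomes the x axis, a cubic polynomial is fitted, and four measurements
# are read off the fitted curve: the negative-rectified area (A_PS), the
# positive-rectified area (A_PC), the completion-to-separation transition
# point (T_PCPS) and the peak separation depth (PS_max).

#' Rotate similarity points clockwise by 45 degrees
#'
#' Maps \code{(S_in, S_out)} to
#' \code{((S_in + S_out)/sqrt(2), (S_out - S_in)/sqrt(2))}, so the rotated
#' ordinate is negative exactly when \code{S_out < S_in} (separation).
#'
#' @param s_in,s_out equal-length numeric vectors.
#' @return data.frame with rotated coordinates \code{x}, \code{y}.
#' @export
rotate_points <- function(s_in, s_out) {
  stopifnot(length(s_in) == length(s_out))
  data.frame(x = (s_in + s_out) / sqrt(2), y = (s_out - s_in) / sqrt(2))
}

#' Least-squares cubic fit
#'
#' Fits \code{y = c0 + c1 x + c2 x^2 + c3 x^3}. With duplicated abscissae or
#' otherwise rank-deficient design the degree is lowered until the fit is
#' full-rank, and the result is flagged.
#'
#' @param x,y numeric vectors (at least 4 points for a full cubic).
#' @return list with \code{coef} (always length 4, constant term first,
#'   missing degrees zero), \code{degree} and \code{degenerate}.
#' @export
fit_cubic <- function(x, y) {
  stopifnot(length(x) == length(y))
  for (deg in 3:0) {
    n_distinct <- length(unique(x))
    if (n_distinct < deg + 1) next
    X <- outer(x, 0:deg, `^`)
    fit <- stats::lm.fit(X, y)
    if (fit$rank == deg + 1) {
      cf <- numeric(4)
      cf[1:(deg + 1)] <- fit$coefficients
      return(list(coef = cf, degree = deg, degenerate = deg < 3))
    }
  }
  list(coef = c(mean(y), 0, 0, 0), degree = 0, degenerate = TRUE)
}

poly_eval <- function(coef, x) {
  coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
}

poly_antideriv <- function(coef, x) {
  coef[1] * x + coef[2] * x^2 / 2 + coef[3] * x^3 / 3 + coef[4] * x^4 / 4
}

# real roots of the fitted polynomial inside (lo, hi)
poly_roots_in <- function(coef, lo, hi, tol = 1e-12) {
  cf <- coef
  while (length(cf) > 1 && abs(cf[length(cf)]) < tol) cf <- cf[-length(cf)]
  if (length(cf) <= 1) return(numeric(0))
  rt <- polyroot(cf)
  re <- Re(rt[abs(Im(rt)) < 1e-8])
  sort(re[re > lo + tol & re < hi - tol])
}

#' Pattern separation measurements from a fitted cubic
#'
#' Computes, over the observed rotated-x range, the exact (analytically
#' integrated) areas of the negative- and positive-rectified polynomial, the
#' completion-to-separation transition point and the peak separation depth.
#'
#' \code{T_PCPS} is the smallest x at which the fitted curve crosses from
#' non-negative (completion side) to negative (separation side), scanning x
#' upward; it equals the range start if the curve is already negative there,
#' and the range end if the curve never becomes negative.
#'
#' @param fit result of \code{\link{fit_cubic}} (or a length-4 coefficient
#'   vector, constant first).
#' @param x_range \code{c(min, max)} of the rotated abscissa.
#' @return list with \code{A_PS}, \code{A_PC}, \code{T_PCPS}, \code{PS_max}
#'   and the \code{coef} used.
#' @export
ps_measurements <- function(fit, x_range) {
  coef <- if (is.list(fit)) fit$coef else {
    stopifnot(length(fit) == 4)
    fit
  }
  lo <- x_range[1]; hi <- x_range[2]
  stopifnot(hi > lo)
  cuts <- c(lo, poly_roots_in(coef, lo, hi), hi)
  A_PS <- 0; A_PC <- 0
  for (i in seq_len(length(cuts) - 1)) {
    a <- cuts[i]; b <- cuts[i + 1]
    area <- poly_antideriv(coef, b) - poly_antideriv(coef, a)
    mid_val <- poly_eval(coef, (a + b) / 2)
    if (mid_val < 0) A_PS <- A_PS - area else A_PC <- A_PC + area
  }
  # peak negative deflection: check segment ends and stationary points
  cand <- c(lo, hi)
  if (abs(coef[4]) > 0 || abs(coef[3]) > 0) {
    dcf <- c(coef[2], 2 * coef[3], 3 * coef[4])
    while (length(dcf) > 1 && abs(dcf[length(dcf)]) < 1e-14)
      dcf <- dcf[-length(dcf)]
    if (length(dcf) > 1) {
      rt <- polyroot(dcf)
      re <- Re(rt[abs(Im(rt)) < 1e-8])
      cand <- c(cand, re[re >= lo & re <= hi])
    }
  }
  PS_max <- max(0, -min(poly_eval(coef, cand)))
  # first +/- crossing scanning upward
  eps <- 1e-12
  if (poly_eval(coef, lo) < -eps) {
    T_PCPS <- lo
  } else {
    T_PCPS <- hi
    roots <- poly_roots_in(coef, lo, hi)
    for (r0 in roots) {
      after <- poly_eval(coef, min(r0 + 1e-6 * (hi - lo), hi))
      if (after < -eps) {
        T_PCPS <- r0
        break
      }
    }
  }
  list(A_PS = A_PS, A_PC = A_PC, T_PCPS = T_PCPS, PS_max = PS_max,
       coef = coef)
}

#' Assemble and quantify an S_out-vs-S_in curve
#'
#' @param s_in,s_out similarity values (one per morph level, including the
#'   self-comparison point).
#' @return list with the rotated points, the cubic fit, and the four
#'   measurements; \code{NULL} measurements if any similarity is undefined.
#' @export
ps_from_curve <- function(s_in, s_out) {
  if (anyNA(s_in) || anyNA(s_out)) {
    return(list(points = NULL, fit = NULL, measurements = NULL,
                defined = FALSE))
  }
  pts <- rotate_points(s_in, s_out)
  fit <- fit_cubic(pts$x, pts$y)
  m <- ps_measurements(fit, range(pts$x))
  list(points = pts, fit = fit, measurements = m, defined = TRUE)
}

#' Validate a network's pattern-separation performance
#'
#' A network is a valid pattern separator only if all four measurements
#' satisfy their bounds under both correlation metrics (eight checks):
#' \code{A_PS > A_PS_min}, \code{A_PC < A_PC_max}, \code{T_PCPS <
#' T_PCPS_max}, \code{PS_max > PS_max_min}. An undefined metric fails.
#'
#' @param meas_r,meas_R measurement lists (from \code{\link{ps_from_curve}}
#'   or \code{\link{ps_measurements}}) for the average-rate and
#'   instantaneous-rate correlation metrics.
#' @param bounds list with \code{A_PS_min}, \code{A_PC_max},
#'   \code{T_PCPS_max}, \code{PS_max_min} (see \code{\link{dg_config}}).
#' @return list with \code{valid} and the named logical \code{checks}.
#' @export
validate_network_ps <- function(meas_r, meas_R, bounds) {
  one <- function(m, tag) {
    vals <- c(m$A_PS, m$A_PC, m$T_PCPS, m$PS_max)
    if (is.null(m) || length(vals) != 4 || anyNA(vals)) {
      ch <- rep(FALSE, 4)
    } else {
      ch <- c(m$A_PS > bounds$A_PS_min,
              m$A_PC < bounds$A_PC_max,
              m$T_PCPS < bounds$T_PCPS_max,
              m$PS_max > bounds$PS_max_min)
    }
    names(ch) <- paste(c("A_PS", "A_PC", "T_PCPS", "PS_max"), tag, sep = "_")
    ch
  }
  mr <- if (!is.null(meas_r$measurements)) meas_r$measurements else meas_r
  mR <- if (!is.null(meas_R$measurements)) meas_R$measurements else meas_R
  checks <- c(one(mr, "r"), one(mR, "R"))
  list(valid = all(checks), checks = checks)
}
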