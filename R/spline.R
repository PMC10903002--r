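# Natural cubic spline with linear extrapolation, in a form that exposes the
# linear dependence of the interpolant on the knot values.  The PMRM likelihood
# and its analytic gradient need, for arbitrary evaluation points x,
#   g(x)        the interpolant value,
#   g'(x)       its derivative (gradient w.r.t. the time warp), and
#   dg(x)/dy    the row of cardinal-basis weights (gradient w.r.t. knot values),
# all of which follow from the classical second-derivative representation:
# M = K y with K a fixed linear map (zero end curvature), and g piecewise cubic
# in (y, M).

# Precompute the knot-value -> second-derivative map K for a fixed knot grid.
ns_prep <- function(t) {
  J <- length(t)
  if (J < 3L) stop("need at least 3 knots for a cubic spline")
  h <- diff(t)
  # tridiagonal system for interior second derivatives M_2..M_{J-1}
  m <- J - 2L
  A <- matrix(0, m, m)
  B <- matrix(0, m, J)
  for (i in seq_len(m)) {
    A[i, i] <- (h[i] + h[i + 1L]) / 3
    if (i > 1L) A[i, i - 1L] <- h[i] / 6
    if (i < m) A[i, i + 1L] <- h[i + 1L] / 6
    B[i, i] <- 1 / h[i]
    B[i, i + 1L] <- -(1 / h[i] + 1 / h[i + 1L])
    B[i, i + 2L] <- 1 / h[i + 1L]
  }
  K <- matrix(0, J, J)
  K[2:(J - 1L), ] <- solve(A, B)
  list(t = t, h = h, K = K, J = J)
}

# Evaluate value, first derivative and basis rows at points x.
# Returns list(value, deriv, basis) with basis a length(x) x J matrix such
# that value == basis %*% y for any knot values y (linearity in y).
ns_eval <- function(prep, y, x, basis = FALSE) {
  t <- prep$t; h <- prep$h; K <- prep$K; J <- prep$J
  M <- drop(K %*% y)
  n <- length(x)
  val <- numeric(n); der <- numeric(n)
  Bm <- if (basis) matrix(0, n, J) else NULL
  sL <- (y[2L] - y[1L]) / h[1L] - M[2L] * h[1L] / 6            # boundary slopes
  sR <- (y[J] - y[J - 1L]) / h[J - 1L] + M[J - 1L] * h[J - 1L] / 6
  left <- x <= t[1L]; right <- x >= t[J]; mid <- !(left | right)
  if (any(left)) {
    dx <- x[left] - t[1L]
    val[left] <- y[1L] + sL * dx; der[left] <- sL
    if (basis) {
      B <- -outer(dx * h[1L] / 6, K[2L, ])
      B[, 1L] <- B[, 1L] + 1 - dx / h[1L]
      B[, 2L] <- B[, 2L] + dx / h[1L]
      Bm[left, ] <- B
    }
  }
  if (any(right)) {
    dx <- x[right] - t[J]
    val[right] <- y[J] + sR * dx; der[right] <- sR
    if (basis) {
      B <- outer(dx * h[J - 1L] / 6, K[J - 1L, ])
      B[, J - 1L] <- B[, J - 1L] - dx / h[J - 1L]
      B[, J] <- B[, J] + 1 + dx / h[J - 1L]
      Bm[right, ] <- B
    }
  }
  if (any(mid)) {
    xm <- x[mid]
    k <- findInterval(xm, t, rightmost.closed = TRUE)
    hk <- h[k]; u <- xm - t[k]; v <- t[k + 1L] - xm
    a <- v^3 / (6 * hk) - hk * v / 6        # coefficient on M_k
    b <- u^3 / (6 * hk) - hk * u / 6        # coefficient on M_{k+1}
    val[mid] <- M[k] * a + M[k + 1L] * b + (y[k] * v + y[k + 1L] * u) / hk
    der[mid] <- (-M[k] * v^2 + M[k + 1L] * u^2) / (2 * hk) +
      (y[k + 1L] - y[k]) / hk - (M[k + 1L] - M[k]) * hk / 6
    if (basis) {
      B <- a * K[k, , drop = FALSE] + b * K[k + 1L, , drop = FALSE]
      i <- seq_len(nrow(B))
      B[cbind(i, k)] <- B[cbind(i, k)] + v / hk
      B[cbind(i, k + 1L)] <- B[cbind(i, k + 1L)] + u / hk
      Bm[mid, ] <- B
    }
  }
  list(value = val, deriv = der, basis = Bm)
}

#' Smooth reference curve through per-visit means
#'
#' Builds the placebo reference trajectory used by the time-based progression
#' model: a natural cubic spline through the per-visit mean CDR-SB values,
#' extrapolated linearly with the boundary slope outside the visit range.
#' With fewer than three visits a linear interpolant is returned with a
#' warning.
#'
#' @param alphas Numeric vector of per-visit mean CDR-SB values.
#' @param visit_months Numeric vector of visit times in months, strictly
#'   increasing, same length as `alphas`.
#' @return A function of one numeric argument (month) returning CDR-SB points.
#' @examples
#' g <- reference_curve(c(1.5, 1.9, 2.4, 4.0), c(0, 6, 12, 18))
#' g(c(0, 9, 18))
#' @export
reference_curve <- function(alphas, visit_months) {
  stopifnot(length(alphas) == length(visit_months),
            !is.unsorted(visit_months, strictly = TRUE))
  if (length(alphas) < 3L) {
    warning("fewer than 3 visits: falling back to linear interpolation")
    return(stats::approxfun(visit_months, alphas, rule = 2))
  }
  prep <- ns_prep(visit_months)
  function(month) ns_eval(prep, alphas, month)$value
}
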