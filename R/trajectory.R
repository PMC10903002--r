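#' Placebo trajectory specification
#'
#' Bundles the generative truth of a simulated trial: mean CDR-SB at each
#' scheduled visit of the placebo arm together with the unstructured temporal
#' covariance of within-subject residuals across visits.
#'
#' @param visit_months Strictly increasing visit times in months; the first
#'   visit must be baseline (month 0).
#' @param placebo_means Non-decreasing mean CDR-SB (points) at each visit.
#' @param covariance Symmetric positive-(semi)definite matrix of residual
#'   variances and covariances across visits (points squared).  A singular
#'   (e.g. all-zero) matrix is accepted as a degenerate noise-free mode;
#'   indefinite or asymmetric matrices are rejected.
#' @return An object of class `trajectory_spec`.
#' @seealso [default_trajectory()] for the packaged fixture.
#' @export
trajectory_spec <- function(visit_months, placebo_means, covariance) {
  visit_months <- as.numeric(visit_months)
  placebo_means <- as.numeric(placebo_means)
  covariance <- as.matrix(covariance)
  J <- length(visit_months)
  if (J < 2L) stop("need at least 2 visits")
  if (is.unsorted(visit_months, strictly = TRUE))
    stop("visit_months must be strictly increasing")
  if (visit_months[1L] != 0) stop("first visit must be baseline (month 0)")
  if (any(visit_months < 0)) stop("visit months must be non-negative")
  if (length(placebo_means) != J)
    stop("placebo_means must have one value per visit")
  if (is.unsorted(placebo_means))
    stop("placebo_means must be non-decreasing (progressive worsening)")
  if (!all(dim(covariance) == c(J, J)))
    stop("covariance must be ", J, "x", J)
  if (max(abs(covariance - t(covariance))) > 1e-8 * (1 + max(abs(covariance))))
    stop("covariance must be symmetric")
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  structure(list(visit_months = visit_months,
                 placebo_means = placebo_means,
                 covariance = covariance),
            class = "trajectory_spec")
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat("Trajectory specification:", length(x$visit_months), "visits\n")
  tab <- rbind(`visit (months)` = x$visit_months,
               `mean CDR-SB` = x$placebo_means,
               `SD` = sqrt(diag(x$covariance)))
  print(round(tab, 3))
  invisible(x)
}

#' Default placebo trajectory fixture
#'
#' A packaged stand-in for the trajectory of an amyloid-positive MCI cohort:
#' baseline mean CDR-SB of 1.5 with an accelerating (convex) worsening over
#' visits at months 0, 6, 12, 18, 24 and 36 (change from baseline 0, 0.15,
#' 0.45, 0.90, 1.45, 2.55 points), and a positive-definite covariance with
#' standard deviations growing from 1.0 to 2.6 points and positive
#' within-subject correlations decaying with the time lag.  These are
#' synthetic fixture values, not estimates from any cohort; override them via
#' [trajectory_spec()] or a configuration file if estimated values are
#' available.
#'
#' @return A `trajectory_spec`.
#' @examples
#' traj <- default_trajectory()
#' diff(traj$placebo_means)  # accelerating decline
#' @export
default_trajectory <- function() {
  visits <- c(0, 6, 12, 18, 24, 36)
  cfb <- c(0, 0.15, 0.45, 0.90, 1.45, 2.55)
  sds <- c(1.0, 1.2, 1.5, 1.8, 2.1, 2.6)
  lag <- abs(outer(visits, visits, "-"))
  corr <- 0.3 + 0.7 * 0.85^(lag / 6)
  diag(corr) <- 1
  trajectory_spec(visits, 1.5 + cfb, outer(sds, sds) * corr)
}

#' Active-arm mean under a proportional time delay
#'
#' The mean CDR-SB of the active arm at a scheduled visit `t` equals the
#' placebo mean trajectory evaluated at `(1 - s) * t`, using piecewise-linear
#' interpolation between scheduled visits.  A slowing fraction `s = 0.2`
#' means the active arm reaches at month `t` the disease state the placebo
#' arm reached at `0.8 * t`.
#'
#' @param traj A [trajectory_spec()].
#' @param slowing_fraction Proportional slowing `s` in `[0, 1)`.
#' @param month Scheduled visit month(s) at which to evaluate.
#' @return Mean CDR-SB points at the requested visit(s).
#' @examples
#' traj <- default_trajectory()
#' active_mean_at(traj, 0.2, 36)
#' @export
active_mean_at <- function(traj, slowing_fraction, month) {
  stopifnot(inherits(traj, "trajectory_spec"))
  check_slowing(slowing_fraction)
  if (!all(month %in% traj$visit_months))
    stop("month must be on the scheduled visit grid (",
         paste(traj$visit_months, collapse = ", "), ")")
  stats::approx(traj$visit_months, traj$placebo_means,
                xout = (1 - slowing_fraction) * month)$y
}

check_slowing <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s >= 1)
    stop("slowing_fraction must be a single number in [0, 1)")
  invisible(s)
}
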