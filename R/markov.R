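#' Specification of the four-state Markov cohort model
#'
#' States are MCI due to AD, mild AD dementia, moderate-to-severe AD
#' dementia, and death, with no back-transitions.  Transition intensities
#' are constant over cycles: state-specific monthly mortality, and annual
#' progression probabilities converted to monthly by
#' [annual_to_monthly()].  The whole cohort starts in MCI.
#'
#' Within a cycle, death and progression compete.  By default death is
#' applied first and progression to the survivors, e.g. the one-cycle
#' probability of moving from MCI to mild dementia is
#' `(1 - 0.003) * annual_to_monthly(0.23)`; the reverse ordering is
#' available via `ordering = "progression_first"`.
#'
#' @param monthly_mortality Monthly death probabilities in the three alive
#'   states (MCI, mild, moderate-to-severe); defaults 0.003, 0.005, 0.010.
#' @param annual_progression Annual probabilities of MCI to mild dementia
#'   and mild to moderate-to-severe dementia; defaults 0.23 and 0.39.
#' @param horizon_months Time horizon (default 180 months = 15 years).
#' @param cycle_length Cycle length in months (default 1).
#' @param slowing_fraction Treatment-arm time-axis stretch `s >= 0`
#'   (default 0.19): cycle `k` of the treatment arm ends at
#'   `(1 + s) * k` months.
#' @param ordering Within-cycle competing-risk ordering; see Details.
#' @return A `markov_spec` list.
#' @export
markov_spec <- function(monthly_mortality = c(0.003, 0.005, 0.010),
                        annual_progression = c(0.23, 0.39),
                        horizon_months = 180,
                        cycle_length = 1,
                        slowing_fraction = 0.19,
                        ordering = c("death_first", "progression_first")) {
  ordering <- match.arg(ordering)
  stopifnot(length(monthly_mortality) == 3L, length(annual_progression) == 2L,
            all(monthly_mortality >= 0), all(monthly_mortality <= 1),
            all(annual_progression >= 0), all(annual_progression < 1),
            horizon_months > 0, cycle_length > 0,
            slowing_fraction >= 0)
  if (abs(horizon_months / cycle_length -
          round(horizon_months / cycle_length)) > 1e-9)
    stop("horizon_months must be a positive multiple of cycle_length")
  structure(list(monthly_mortality = monthly_mortality,
                 annual_progression = annual_progression,
                 horizon_months = horizon_months,
                 cycle_length = cycle_length,
                 slowing_fraction = slowing_fraction,
                 ordering = ordering),
            class = "markov_spec")
}

#' Convert an annual transition probability to a monthly one
#'
#' Uses the constant-intensity relation `1 - (1 - p)^(1/12)`.
#'
#' @param p_annual Annual probability in `[0, 1)`.
#' @return Monthly probability.
#' @examples
#' annual_to_monthly(0.23)
#' @export
annual_to_monthly <- function(p_annual) {
  if (any(p_annual < 0) || any(p_annual >= 1))
    stop("annual probability must be in [0, 1) (p = 1 has no finite intensity)")
  1 - (1 - p_annual)^(1 / 12)
}

markov_transition <- function(spec) {
  pd <- spec$monthly_mortality
  q <- annual_to_monthly(spec$annual_progression)
  P <- matrix(0, 4L, 4L,
              dimnames = list(NULL, c("mci", "mild", "modsev", "dead")))
  if (spec$ordering == "death_first") {
    P[1L, 4L] <- pd[1L]; P[1L, 2L] <- (1 - pd[1L]) * q[1L]
    P[2L, 4L] <- pd[2L]; P[2L, 3L] <- (1 - pd[2L]) * q[2L]
  } else {
    P[1L, 2L] <- q[1L]; P[1L, 4L] <- (1 - q[1L]) * pd[1L]
    P[2L, 3L] <- q[2L]; P[2L, 4L] <- (1 - q[2L]) * pd[2L]
  }
  P[3L, 4L] <- pd[3L]
  P[1L, 1L] <- 1 - sum(P[1L, -1L]); P[2L, 2L] <- 1 - sum(P[2L, c(3L, 4L)])
  P[3L, 3L] <- 1 - pd[3L]; P[4L, 4L] <- 1
  P
}

markov_run <- function(spec, stretch) {
  K <- as.integer(round(spec$horizon_months / spec$cycle_length))
  P <- markov_transition(spec)
  x <- matrix(0, K + 1L, 4L, dimnames = list(NULL, colnames(P)))
  x[1L, 1L] <- 1
  for (k in seq_len(K)) x[k + 1L, ] <- x[k, ] %*% P
  L <- spec$cycle_length * (1 + stretch)
  b <- pmin(spec$horizon_months, L * (0:K))     # within-horizon boundary times
  cl <- diff(b)                                  # within-horizon cycle lengths
  # trapezoid (half-cycle) weights: each boundary carries half of each
  # adjacent within-horizon cycle; first and last cycles thus get weight 1/2
  dt <- c(cl[1L] / 2, (cl[-1L] + cl[-K]) / 2, cl[K] / 2)
  tis <- colSums(x * dt)
  structure(list(trace = x,
                 times = L * (0:K),
                 time_in_state = tis[1:3],
                 overall_survival = sum(tis[1:3]),
                 slowing_fraction = stretch,
                 spec = spec),
            class = "markov_result")
}

#' Run the Markov cohort model for the placebo arm
#'
#' Iterates the monthly transition matrix from the all-MCI start over the
#' horizon and integrates state occupancy into expected time per state with
#' half-cycle correction (first and last cycle weighted one half).
#'
#' @param spec A [markov_spec()].
#' @return A `markov_result` with `trace` (per-cycle occupancy fractions,
#'   rows summing to 1), `times` (cycle boundary times in months),
#'   `time_in_state` (months in MCI, mild and moderate-to-severe dementia)
#'   and `overall_survival` (restricted mean months alive within the
#'   horizon).
#' @examples
#' run_placebo(markov_spec())$overall_survival
#' @export
run_placebo <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  markov_run(spec, stretch = 0)
}

#' Run the treatment arm with a stretched time axis
#'
#' The treatment arm traverses exactly the placebo state-occupancy trace,
#' but each cycle lasts `(1 + s)` times longer, so cycle `k` ends at
#' `(1 + s) * k` months: the slowing persists through the horizon and so
#' indirectly delays all transitions, including to death.  Time in state
#' integrates occupancy over the stretched cycle lengths, truncated at the
#' horizon (the cycle straddling the horizon contributes only its
#' within-horizon fraction), with the same half-cycle correction as the
#' placebo arm.
#'
#' @param spec A [markov_spec()]; `spec$slowing_fraction` is the stretch.
#' @return A `markov_result`; see [run_placebo()].
#' @examples
#' run_treatment_time_stretch(markov_spec())$overall_survival
#' @export
run_treatment_time_stretch <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  if (spec$slowing_fraction < 0) stop("slowing_fraction must be non-negative")
  markov_run(spec, stretch = spec$slowing_fraction)
}

#' Extract the slowing fraction from a PMRM fit
#'
#' Returns the estimated percent slowing at the final visit (delay in months
#' divided by the visit month) for use as the Markov time-axis stretch.  The
#' unrounded value is returned by default; `rounded = TRUE` rounds to whole
#' percent as used in reporting.
#'
#' @param fit A converged [fit_pmrm()] result.
#' @param rounded Round to whole percent?
#' @return The slowing fraction (dimensionless).
#' @export
from_pmrm <- function(fit, rounded = FALSE) {
  stopifnot(inherits(fit, "pmrm_fit"))
  if (!fit$converged) stop("PMRM fit did not converge")
  s <- unname(fit$percent_slowing[length(fit$percent_slowing)])
  if (rounded) round(s, 2) else s
}

#' @export
print.markov_result <- function(x, ...) {
  cat(sprintf("Markov cohort result (time-axis stretch %.0f%%):\n",
              100 * x$slowing_fraction))
  tis <- c(x$time_in_state, `overall survival` = x$overall_survival)
  print(round(tis, 1))
  cat("(months within a", x$spec$horizon_months, "month horizon)\n")
  invisible(x)
}
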