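#' Dichotomize trajectories into progression-to-dementia events
#'
#' Progression to dementia is defined as reaching a CDR-SB at or above the
#' threshold (default 4.5 points) at a post-baseline visit.  The event time
#' is the first post-baseline visit month at which the threshold is reached;
#' subjects who never cross are censored at their last observed visit.
#' Baseline values are never events, even if they exceed the threshold
#' (possible under the unclipped continuous simulation).  Events are placed
#' at the discrete visit times with no interval-censoring correction.
#'
#' @param data A `trial_data` long-format data frame.
#' @param threshold CDR-SB points defining dementia onset (default 4.5).
#' @return A `progression_events` data frame with one row per subject:
#'   `subject_id`, `arm`, `event_time` (months) and `event` (1 = progressed,
#'   0 = censored).
#' @examples
#' trial <- generate_trial(default_trajectory(), 0.2, 50, 36, seed = 3)
#' ev <- dichotomize_progression(trial)
#' table(ev$arm, ev$event)
#' @export
dichotomize_progression <- function(data, threshold = 4.5) {
  stopifnot(is.data.frame(data), is.numeric(threshold), length(threshold) == 1L)
  d <- data[order(data$subject_id, data$visit_month), ]
  post <- d[d$visit_month > 0, ]
  if (nrow(post) == 0L) stop("no post-baseline visits present")
  sp <- split(seq_len(nrow(post)), post$subject_id)
  first_id <- vapply(sp, function(i) {
    hit <- i[post$cdr_sb[i] >= threshold]
    if (length(hit)) hit[1L] else i[length(i)]
  }, 0L)
  out <- data.frame(
    subject_id = post$subject_id[first_id],
    arm = post$arm[first_id],
    event_time = post$visit_month[first_id],
    event = as.integer(post$cdr_sb[first_id] >= threshold))
  rownames(out) <- NULL
  class(out) <- c("progression_events", "data.frame")
  out
}

#' Cox proportional-hazards fit on progression events
#'
#' Partial-likelihood fit of the treatment-arm indicator on time to
#' progression, with Efron's method (default) for the heavy ties that arise
#' from events placed at a handful of discrete visit times.  The hazard
#' ratio is for the active arm relative to placebo; a value below 1 means a
#' reduced risk of progressing to dementia.
#'
#' @param events A `progression_events` data frame from
#'   [dichotomize_progression()].
#' @param ties Tie-handling method passed to [survival::coxph()]; `"efron"`
#'   (default) or `"breslow"`.
#' @return An object of class `cox_fit` with `hazard_ratio`, `log_hr`,
#'   `log_hr_se`, `wald_p`, `n_events` (per arm) and `estimable`.
#' @export
fit_cox <- function(events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(events),
            all(c("arm", "event_time", "event") %in% names(events)))
  n_events <- c(placebo = sum(events$event[events$arm == "placebo"]),
                active = sum(events$event[events$arm == "active"]))
  res <- structure(list(hazard_ratio = NA_real_, log_hr = NA_real_,
                        log_hr_se = NA_real_, wald_p = NA_real_,
                        n_events = n_events, ties = ties,
                        estimable = FALSE),
                   class = "cox_fit")
  if (sum(n_events) < 1L) return(res)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(event_time, event) ~ arm, data = events, ties = ties)),
    error = function(e) NULL)
  if (is.null(fit)) return(res)
  beta <- unname(stats::coef(fit)[1L])
  se <- sqrt(diag(fit$var))[1L]
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) return(res)
  res$hazard_ratio <- exp(beta)
  res$log_hr <- beta
  res$log_hr_se <- se
  res$wald_p <- 2 * stats::pnorm(-abs(beta / se))
  res$estimable <- TRUE
  res
}

#' @export
print.cox_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("Cox fit: not estimable (",
        sum(x$n_events), " events)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Cox fit (%s ties): HR %.3f (log HR %.3f, SE %.3f), p %s\n",
              x$ties, x$hazard_ratio, x$log_hr, x$log_hr_se,
              format.pval(x$wald_p)))
  cat("events: placebo", x$n_events["placebo"],
      "/ active", x$n_events["active"], "\n")
  invisible(x)
}
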