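#' Scenario grid for the replication harness
#'
#' @param n_per_arm Sample sizes per arm to sweep (default 200-700).
#' @param duration_months Trial durations to sweep (default 18, 24, 36);
#'   each must be a scheduled visit month of the trajectory used.
#' @param n_replicates Simulated trials per scenario.  The default of 200 is
#'   a desk-scale compromise (Monte Carlo error of about one point on a
#'   median effect and about 0.03-0.04 on a power estimate); raise to 1000
#'   for publication-grade tables.
#' @param master_seed Integer master seed; per-replicate seeds are derived
#'   deterministically from it, so results do not depend on execution order.
#' @return A `scenario_grid` list.
#' @export
scenario_grid <- function(n_per_arm = c(200, 300, 400, 500, 600, 700),
                          duration_months = c(18, 24, 36),
                          n_replicates = 200,
                          master_seed = 1L) {
  stopifnot(all(n_per_arm >= 2), all(duration_months > 0), n_replicates >= 1)
  structure(list(n_per_arm = as.integer(n_per_arm),
                 duration_months = as.numeric(duration_months),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed)),
            class = "scenario_grid")
}

#' Run the simulation study across a scenario grid
#'
#' For every combination of sample size and trial duration, generates
#' `n_replicates` trials with the given trajectory and true proportional
#' slowing, fits the time-based PMRM, the longitudinal score-scale
#' comparator and the Cox model on dichotomized progression to each, and
#' aggregates median effect estimates (PMRM percent time delay at the final
#' visit, MMRM percent CFB reduction at the final visit, Cox hazard ratio)
#' and empirical power (fraction of replicates with a two-sided Wald p-value
#' below `alpha`).  Medians and power are computed over converged fits only;
#' a convergence rate below 95% in any scenario aborts (or warns, see
#' `on_low_convergence`).
#'
#' @param grid A [scenario_grid()].
#' @param traj A [trajectory_spec()] covering the longest duration.
#' @param slowing_fraction True proportional slowing in `[0, 1)`.
#' @param threshold CDR-SB threshold for progression to dementia.
#' @param mmrm_method Passed to [fit_mmrm()].
#' @param alpha Two-sided significance level defining the power event.
#' @param on_low_convergence `"error"` (default) or `"warn"`.
#' @param progress Print a line per scenario as it completes.
#' @return A `study_result` list with `replicates` (one row per scenario,
#'   replicate and model quantity), `medians`, `power`, `convergence` and
#'   the `grid`.
#' @export
run_study <- function(grid, traj, slowing_fraction,
                      threshold = 4.5, mmrm_method = "clda",
                      alpha = 0.05,
                      on_low_convergence = c("error", "warn"),
                      progress = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"), inherits(traj, "trajectory_spec"))
  on_low_convergence <- match.arg(on_low_convergence)
  if (!all(grid$duration_months %in% traj$visit_months))
    stop("every duration must be a scheduled visit month of the trajectory")
  scen <- expand.grid(n_per_arm = grid$n_per_arm,
                      duration = grid$duration_months,
                      KEEP.OUT.ATTRS = FALSE)
  reps <- vector("list", nrow(scen))
  for (i in seq_len(nrow(scen))) {
    n <- scen$n_per_arm[i]; dur <- scen$duration[i]
    out <- matrix(NA_real_, grid$n_replicates, 9L)
    colnames(out) <- c("pmrm_pct", "pmrm_p", "pmrm_conv",
                       "mmrm_pct", "mmrm_p", "mmrm_conv",
                       "cox_hr", "cox_p", "cox_conv")
    for (r in seq_len(grid$n_replicates)) {
      seed <- replicate_seed(grid$master_seed, i, r)
      trial <- generate_trial(traj, slowing_fraction, n, dur, seed)
      pf <- tryCatch(fit_pmrm(trial), error = function(e) NULL)
      if (!is.null(pf) && pf$converged && pf$se_available) {
        J <- length(pf$delays)
        out[r, 1:3] <- c(100 * pf$percent_slowing[J], pf$wald_p_final, 1)
      } else out[r, 3L] <- 0
      mf <- tryCatch(fit_mmrm(trial, method = mmrm_method),
                     error = function(e) NULL)
      if (!is.null(mf) && mf$converged) {
        out[r, 4:6] <- c(100 * mf$percent_reduction, mf$wald_p_final, 1)
      } else out[r, 6L] <- 0
      cf <- tryCatch(fit_cox(dichotomize_progression(trial, threshold)),
                     error = function(e) NULL)
      if (!is.null(cf) && cf$estimable) {
        out[r, 7:9] <- c(cf$hazard_ratio, cf$wald_p, 1)
      } else out[r, 9L] <- 0
    }
    reps[[i]] <- data.frame(n_per_arm = n, duration = dur,
                            replicate = seq_len(grid$n_replicates), out)
    if (progress)
      message(sprintf("scenario n=%d, %g months done", n, dur))
  }
  replicates <- do.call(rbind, reps)

  agg <- lapply(seq_len(nrow(scen)), function(i) {
    d <- reps[[i]]
    conv <- c(pmrm = mean(d$pmrm_conv), mmrm = mean(d$mmrm_conv),
              cox = mean(d$cox_conv))
    data.frame(
      n_per_arm = scen$n_per_arm[i], duration = scen$duration[i],
      pmrm_pct_delay = stats::median(d$pmrm_pct[d$pmrm_conv == 1]),
      mmrm_pct_reduction = stats::median(d$mmrm_pct[d$mmrm_conv == 1]),
      cox_hr = stats::median(d$cox_hr[d$cox_conv == 1]),
      pmrm_power = mean(d$pmrm_p[d$pmrm_conv == 1] < alpha),
      mmrm_power = mean(d$mmrm_p[d$mmrm_conv == 1] < alpha),
      cox_power = mean(d$cox_p[d$cox_conv == 1] < alpha),
      pmrm_convergence = conv["pmrm"], mmrm_convergence = conv["mmrm"],
      cox_convergence = conv["cox"], row.names = NULL)
  })
  agg <- do.call(rbind, agg)
  low <- agg[agg$pmrm_convergence < 0.95 | agg$mmrm_convergence < 0.95 |
               agg$cox_convergence < 0.95, , drop = FALSE]
  if (nrow(low) > 0L) {
    msg <- paste0("convergence rate below 95% in scenario(s): ",
                  paste(sprintf("n=%d/%gm", low$n_per_arm, low$duration),
                        collapse = ", "))
    if (on_low_convergence == "error") stop(msg) else warning(msg)
  }
  structure(list(
    grid = grid,
    replicates = replicates,
    medians = agg[, c("n_per_arm", "duration", "pmrm_pct_delay",
                      "mmrm_pct_reduction", "cox_hr")],
    power = agg[, c("n_per_arm", "duration", "pmrm_power", "mmrm_power",
                    "cox_power")],
    convergence = agg[, c("n_per_arm", "duration", "pmrm_convergence",
                          "mmrm_convergence", "cox_convergence")]),
    class = "study_result")
}

# deterministic per-replicate substream seed, independent of execution order
replicate_seed <- function(master, scenario_index, replicate) {
  as.integer((as.double(master) + 104729 * scenario_index + replicate - 1) %%
               2147483629)
}

#' Format study results as publication-style tables
#'
#' Produces a medians table (rows are scenarios; percent effects to whole
#' percent, hazard ratios to two decimals) and an empirical power table, both
#' as data frames of formatted strings plus plain-text renderings.
#'
#' @param res A [run_study()] result, or one with zero scenarios.
#' @return A list with `medians`, `power` (formatted data frames) and
#'   `medians_text`, `power_text` (character vectors, one line per row
#'   including a header).
#' @export
render_tables <- function(res) {
  stopifnot(inherits(res, "study_result"))
  m <- res$medians; p <- res$power
  fm <- data.frame(
    n_per_arm = m$n_per_arm, duration = m$duration,
    pmrm_pct_delay = sprintf("%.0f%%", m$pmrm_pct_delay),
    mmrm_pct_reduction = sprintf("%.0f%%", m$mmrm_pct_reduction),
    cox_hr = sprintf("%.2f", m$cox_hr))
  fp <- data.frame(
    n_per_arm = p$n_per_arm, duration = p$duration,
    pmrm_power = sprintf("%.0f%%", 100 * p$pmrm_power),
    mmrm_power = sprintf("%.0f%%", 100 * p$mmrm_power),
    cox_power = sprintf("%.0f%%", 100 * p$cox_power))
  if (nrow(m) == 0L) fm <- fm[0L, , drop = FALSE]
  if (nrow(p) == 0L) fp <- fp[0L, , drop = FALSE]
  as_text <- function(d) {
    c(paste(names(d), collapse = ","),
      if (nrow(d)) apply(d, 1L, paste, collapse = ","))
  }
  list(medians = fm, power = fp,
       medians_text = as_text(fm), power_text = as_text(fp))
}

#' Write study tables and replicate-level estimates to a directory
#'
#' @param res A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_tables <- function(res, dir) {
  stopifnot(inherits(res, "study_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(res$medians, file.path(dir, "medians.csv"),
                   row.names = FALSE)
  utils::write.csv(res$power, file.path(dir, "power.csv"), row.names = FALSE)
  utils::write.csv(res$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Simulation study:", nrow(x$medians), "scenarios x",
      x$grid$n_replicates, "replicates\n\nMedian effects:\n")
  print(x$medians, row.names = FALSE, digits = 3)
  cat("\nEmpirical power:\n")
  print(x$power, row.names = FALSE, digits = 3)
  invisible(x)
}
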