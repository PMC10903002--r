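#' Read a simulation configuration file
#'
#' The configuration is plain YAML with keys `visit_months`,
#' `placebo_means`, `covariance` (a list of matrix rows),
#' `slowing_fraction`, `n_per_arm`, `duration_months`, `n_replicates` and
#' `seed`.  Missing trajectory keys fall back to the packaged
#' [default_trajectory()]; missing scenario keys fall back to the
#' [scenario_grid()] defaults.  Users holding estimated visit means and a
#' covariance matrix for a real cohort can supply them here and rerun the
#' whole pipeline unchanged.
#'
#' @param path Path to a YAML file; see
#'   `system.file("extdata", "default_config.yaml", package = "progdelay")`
#'   for a template.
#' @return A list with `trajectory` (a [trajectory_spec()]),
#'   `slowing_fraction`, and a [scenario_grid()] in `grid`.
#' @export
read_trial_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_trajectory()
  visits <- cfg$visit_months %||% defaults$visit_months
  means <- cfg$placebo_means %||% defaults$placebo_means
  covm <- if (is.null(cfg$covariance)) defaults$covariance
          else do.call(rbind, lapply(cfg$covariance, as.numeric))
  traj <- trajectory_spec(visits, means, covm)
  grid <- scenario_grid(
    n_per_arm = cfg$n_per_arm %||% c(200, 300, 400, 500, 600, 700),
    duration_months = cfg$duration_months %||% c(18, 24, 36),
    n_replicates = cfg$n_replicates %||% 200,
    master_seed = cfg$seed %||% 1L)
  list(trajectory = traj,
       slowing_fraction = cfg$slowing_fraction %||% 0.20,
       grid = grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
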