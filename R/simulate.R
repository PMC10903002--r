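#' Simulate a two-arm trial with a proportional time-delay effect
#'
#' Draws each subject's CDR-SB vector over the scheduled visits up to
#' `duration_months` from a multivariate normal distribution: the placebo arm
#' around the placebo means, the active arm around the placebo trajectory
#' evaluated at `(1 - s)` times each visit month (linear interpolation, see
#' [active_mean_at()]), both with the covariance sub-matrix for the included
#' visits.  Scores are left continuous and are neither rounded to the
#' instrument's half-point grid nor truncated to the 0-18 scale range; no
#' dropout is simulated.
#'
#' @param traj A [trajectory_spec()].
#' @param slowing_fraction True proportional slowing `s` in `[0, 1)`.
#' @param n_per_arm Subjects per arm (at least 2).
#' @param duration_months Trial duration; must equal one of the scheduled
#'   visit months.
#' @param seed Integer seed; identical seeds reproduce the dataset exactly.
#' @return A `trial_data` data frame in long format with columns
#'   `subject_id`, `arm` (factor, `placebo`/`active`), `visit_month`,
#'   `cdr_sb`, and attributes `seed`, `n_per_arm`, `duration_months` and
#'   `visit_months`.
#' @examples
#' trial <- generate_trial(default_trajectory(), 0.2, 50, 36, seed = 1)
#' nrow(trial)  # 100 subjects x 6 visits
#' @export
generate_trial <- function(traj, slowing_fraction, n_per_arm,
                           duration_months, seed) {
  stopifnot(inherits(traj, "trajectory_spec"))
  check_slowing(slowing_fraction)
  if (n_per_arm < 2L) stop("n_per_arm must be at least 2")
  if (!(duration_months %in% traj$visit_months))
    stop("duration_months must be one of the scheduled visits (",
         paste(traj$visit_months, collapse = ", "), ")")
  keep <- traj$visit_months <= duration_months
  visits <- traj$visit_months[keep]
  J <- length(visits)
  mu_p <- traj$placebo_means[keep]
  mu_a <- active_mean_at(traj, slowing_fraction, visits)
  Sig <- traj$covariance[keep, keep, drop = FALSE]
  rt <- psd_sqrt(Sig)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")

  n <- as.integer(n_per_arm)
  Z <- matrix(stats::rnorm(2L * n * J), 2L * n, J)
  Y <- Z %*% rt
  Y[seq_len(n), ] <- sweep(Y[seq_len(n), , drop = FALSE], 2L, mu_p, "+")
  Y[n + seq_len(n), ] <- sweep(Y[n + seq_len(n), , drop = FALSE], 2L, mu_a, "+")

  out <- data.frame(
    subject_id = rep(seq_len(2L * n), each = J),
    arm = factor(rep(c("placebo", "active"), each = n * J),
                 levels = c("placebo", "active")),
    visit_month = rep(visits, times = 2L * n),
    cdr_sb = as.vector(t(Y)))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_per_arm") <- n
  attr(out, "duration_months") <- duration_months
  attr(out, "visit_months") <- visits
  class(out) <- c("trial_data", "data.frame")
  out
}

# symmetric square root tolerating semi-definite matrices (noise-free mode)
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("covariance is not positive semi-definite")
  v <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(v) * t(e$vectors)))
}

#' Write or read a trial dataset as long-format CSV
#'
#' The on-disk format is a plain CSV with header
#' `subject_id,arm,visit_month,cdr_sb`.
#'
#' @param trial A `trial_data` data frame.
#' @param path File path.
#' @return `read_trial` returns a `trial_data` data frame; `write_trial`
#'   returns `path` invisibly.
#' @export
write_trial <- function(trial, path) {
  utils::write.csv(as.data.frame(trial)[, c("subject_id", "arm",
                                            "visit_month", "cdr_sb")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "visit_month", "cdr_sb")
  if (!all(need %in% names(d)))
    stop("trial CSV must have columns ", paste(need, collapse = ", "))
  d$arm <- factor(d$arm, levels = c("placebo", "active"))
  if (anyNA(d$arm)) stop("arm must be 'placebo' or 'active'")
  visits <- sort(unique(d$visit_month))
  attr(d, "visit_months") <- visits
  attr(d, "duration_months") <- max(visits)
  attr(d, "n_per_arm") <- length(unique(d$subject_id[d$arm == "placebo"]))
  class(d) <- c("trial_data", "data.frame")
  d
}

# long trial data -> list with visit grid and per-arm wide matrices
trial_wide <- function(data) {
  stopifnot(is.data.frame(data))
  visits <- sort(unique(data$visit_month))
  J <- length(visits)
  d <- data[order(data$subject_id, data$visit_month), ]
  cnt <- table(d$subject_id)
  if (any(cnt != J))
    stop("every subject must have one record per scheduled visit")
  ids <- unique(d$subject_id)
  Y <- matrix(d$cdr_sb, ncol = J, byrow = TRUE)
  arm <- d$arm[match(ids, d$subject_id)]
  if (nlevels(droplevels(arm)) != 2L) stop("both arms must be present")
  list(visits = visits,
       Yp = Y[arm == "placebo", , drop = FALSE],
       Ya = Y[arm == "active", , drop = FALSE])
}
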