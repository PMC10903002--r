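# shared fixtures: small trajectories with known algebraic behavior

# linear mean trajectory: time delay and score reduction coincide
linear_traj <- function(noise = 0) {
  trajectory_spec(c(0, 12, 24, 36), c(0, 1, 2, 3), diag(noise, 4))
}

# strongly convex 4-visit trajectory from the worked interpolation example
convex_traj <- function(noise = 0) {
  trajectory_spec(c(0, 12, 24, 36), c(0, 0.3, 1.0, 2.2), diag(noise, 4))
}

# gently convex 6-visit trajectory (quadratic change from baseline): close
# enough to its spline interpolant that noise-free warp inversion recovers
# the generative slowing to within a percentage point at every visit
gentle_traj <- function(noise = 0) {
  v <- c(0, 6, 12, 18, 24, 36)
  trajectory_spec(v, 1.5 + 0.06 * v + 0.0004 * v^2, diag(noise, 6))
}

# noise-free copy of the packaged fixture
fixture_zero_noise <- function() {
  traj <- default_trajectory()
  trajectory_spec(traj$visit_months, traj$placebo_means,
                  matrix(0, length(traj$visit_months),
                         length(traj$visit_months)))
}

# Efron partial likelihood for a single binary covariate, written directly
# from its definition (loops over event times and tied sets); independent of
# survival::coxph
efron_loglik <- function(beta, time, status, z) {
  ll <- 0
  for (tt in sort(unique(time[status == 1]))) {
    dead <- which(time == tt & status == 1)
    risk <- which(time >= tt)
    d <- length(dead)
    num <- sum(beta * z[dead])
    sr <- sum(exp(beta * z[risk]))
    sd <- sum(exp(beta * z[dead]))
    ll <- ll + num - sum(log(sr - (seq_len(d) - 1) / d * sd))
  }
  ll
}
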