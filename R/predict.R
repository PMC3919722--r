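#' Expected collective evacuation curve
#'
#' Forward-predicts the expected number of agents still AtHome at the start
#' of every interval of a scenario from a decision model, by the recursion
#' `H[t+1] = H[t] * (1 - r(q[t]; B, T(t)))` starting from the full group.
#' The recursion predicts *decisions*: it deliberately ignores whether a
#' given evacuee finds a bed, since shelter capacity truncates bed
#' assignment, not departures. The maximum rate switches from the T1 to the
#' T2 value at the 30-second mark in VariableTime runs. The recursion is
#' linear in the initial headcount.
#'
#' @param model an [evac_model()] or an `evac_fit`.
#' @param config a `run_config` (needs the trajectory and capacity).
#' @return A data frame of class `prediction_series` with columns `t`
#'   (0 to `end_time`), `at_home` (expected count, starting at the group
#'   size), and `cum_evac` (expected cumulative evacuations).
#' @export
expected_at_home <- function(model, config) {
  if (inherits(model, "evac_fit")) model <- as_evac_model(model)
  stopifnot(inherits(model, "evac_model"), inherits(config, "run_config"))
  traj <- config$trajectory
  r <- evac_rate(model, traj$q_display, config$capacity,
                 time_window(seq_len(traj$end_time), traj$regime))
  H <- config$n_agents * cumprod(1 - r)
  out <- data.frame(t = 0:traj$end_time,
                    at_home = c(config$n_agents, H))
  out$cum_evac <- config$n_agents - out$at_home
  class(out) <- c("prediction_series", "data.frame")
  attr(out, "run_id") <- config$run_id
  out
}

#' Observed at-home counts of a run
#'
#' @param log a `run_log`.
#' @return Integer vector of length `end_time + 1`: agents AtHome at
#'   t = 0, 1, ..., end_time.
#' @export
observed_at_home <- function(log) {
  stopifnot(inherits(log, "run_log"))
  last <- log$at_home[log$end_time] -
    sum(!is.na(log$evac_time) & log$evac_time == log$end_time)
  c(log$at_home, last)
}

#' Compare a predicted curve with an observed run
#'
#' Residuals between the expected and observed cumulative-evacuation
#' curves, with RMSE and maximum absolute deviation summaries.
#'
#' @param pred a `prediction_series` from [expected_at_home()].
#' @param log the matching `run_log` (same run id and horizon).
#' @return A list: `residuals` (per-second, observed - predicted), `rmse`,
#'   `max_deviation`.
#' @export
compare_runs <- function(pred, log) {
  stopifnot(inherits(pred, "prediction_series"), inherits(log, "run_log"))
  if (!identical(as.numeric(attr(pred, "run_id")), as.numeric(log$run_id)))
    stop("run_id mismatch between prediction and log")
  obs <- observed_at_home(log)
  if (length(obs) != nrow(pred)) stop("horizon mismatch")
  resid <- (log$n_agents - obs) - pred$cum_evac
  list(residuals = resid, rmse = sqrt(mean(resid^2)),
       max_deviation = max(abs(resid)))
}

#' Payoff of a strict threshold policy
#'
#' Evaluates, for each candidate threshold, a solo model player who
#' evacuates at the first second the *displayed* likelihood strictly
#' exceeds the threshold (and then reaches the shelter: capacity and time
#' pressure are ignored in this evaluation), scored against every run in a
#' design with that run's own loss matrix. Because the displayed likelihood
#' takes only 11 values, the payoff curve is piecewise constant with
#' breakpoints at those levels; a threshold of 1.0 never evacuates.
#'
#' @param theta_grid thresholds to evaluate (nonempty, in \[0, 1\]).
#' @param design list of `run_config`s.
#' @return Data frame with columns `theta` and `score` (total points
#'   retained over the design).
#' @export
strict_threshold_payoff <- function(theta_grid, design) {
  if (!length(theta_grid)) stop("`theta_grid` is empty")
  score_one <- function(theta, cfg) {
    hit <- cfg$trajectory$outcome == "Hit"
    state <- if (any(cfg$trajectory$q_display > theta)) "InShelter" else "AtHome"
    100 - cfg$loss[state, if (hit) "Hit" else "Miss"]
  }
  data.frame(theta = theta_grid,
             score = vapply(theta_grid, function(th)
               sum(vapply(design, function(cfg) score_one(th, cfg), numeric(1))),
               numeric(1)))
}
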