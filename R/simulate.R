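#' Simulate one evacuation run
#'
#' Plays a configured scenario forward: each second, every at-home agent
#' evacuates with probability given by the decision law at the displayed
#' likelihood, the shelter capacity, and the time-urgency window. Evacuees
#' claim shelter beds in uniformly random within-second order until the
#' shelter fills; later evacuees remain InTransit. Evacuation is binding:
#' once an agent leaves home it never returns.
#'
#' @param config a `run_config` from [make_design()].
#' @param model an [evac_model()].
#' @param seed optional integer seed.
#' @return An object of class `run_log`: fields `run_id`, `n_agents`,
#'   `end_time`, `outcome`, `regime`, `capacity`, `evac_time` (second of
#'   evacuation per agent, `NA` if never), `bed` (claimed bed index or `NA`),
#'   `final_state`, `at_home` (count at the start of each interval), and the
#'   generating `config`.
#' @export
simulate_run <- function(config, model, seed = NULL) {
  stopifnot(inherits(config, "run_config"), inherits(model, "evac_model"))
  if (!is.null(seed)) set.seed(seed)
  traj <- config$trajectory
  n <- config$n_agents
  B <- config$capacity
  windows <- time_window(seq_len(traj$end_time), traj$regime)
  rate_t <- evac_rate(model, traj$q_display, B, windows)

  evac_time <- rep(NA_integer_, n)
  bed <- rep(NA_integer_, n)
  at_home <- integer(traj$end_time)
  home <- rep(TRUE, n)
  beds_filled <- 0L
  for (t in seq_len(traj$end_time)) {
    at_home[t] <- sum(home)
    idx <- which(home)
    if (length(idx)) {
      leavers <- idx[stats::runif(length(idx)) < rate_t[t]]
      if (length(leavers)) {
        leavers <- if (length(leavers) > 1L) sample(leavers) else leavers
        evac_time[leavers] <- t
        n_bed <- min(length(leavers), B - beds_filled)
        if (n_bed > 0L) {
          bed[leavers[seq_len(n_bed)]] <- beds_filled + seq_len(n_bed)
          beds_filled <- beds_filled + n_bed
        }
        home[leavers] <- FALSE
      }
    }
  }
  final_state <- ifelse(is.na(evac_time), "AtHome",
                        ifelse(is.na(bed), "InTransit", "InShelter"))
  structure(list(run_id = config$run_id, n_agents = n,
                 end_time = traj$end_time, outcome = traj$outcome,
                 regime = traj$regime, capacity = B,
                 evac_time = evac_time, bed = bed, final_state = final_state,
                 at_home = at_home, config = config, seed = seed),
            class = "run_log")
}

#' @export
print.run_log <- function(x, ...) {
  cat(sprintf("Run %s (%s, %d beds): %s at %d s; %d evacuated (%d sheltered, %d in transit)\n",
              x$run_id, x$regime, x$capacity, x$outcome, x$end_time,
              sum(!is.na(x$evac_time)), sum(!is.na(x$bed)),
              sum(x$final_state == "InTransit")))
  invisible(x)
}

#' Tidy per-second panel of a run log
#'
#' Expands a run log into one row per (interval, participant) with the
#' participant state at the start of the interval, the evacuation-event
#' indicator, the displayed likelihood, the time-urgency window, and the
#' number of beds filled at the start of the interval.
#'
#' @param x a `run_log`.
#' @param ... unused.
#' @export
as.data.frame.run_log <- function(x, ...) {
  traj <- x$config$trajectory
  tt <- rep(seq_len(x$end_time), each = x$n_agents)
  pid <- rep(seq_len(x$n_agents), times = x$end_time)
  ev <- x$evac_time[pid]
  state <- ifelse(is.na(ev) | ev >= tt, "AtHome",
                  ifelse(is.na(x$bed[pid]), "InTransit", "InShelter"))
  beds_per_t <- vapply(seq_len(x$end_time), function(t)
    sum(!is.na(x$bed) & x$evac_time < t), integer(1))
  data.frame(run_id = x$run_id, t = tt, participant = pid, state = state,
              evac_event = as.integer(!is.na(ev) & ev == tt),
              q_display = traj$q_display[tt],
              regime_window = time_window(tt, x$regime),
              capacity = x$capacity, beds_filled = beds_per_t[tt])
}

#' Score a completed run
#'
#' Each participant keeps `100 - loss[final_state, outcome]` points.
#'
#' @param log a `run_log`.
#' @param config the matching `run_config` (defaults to the one stored in
#'   the log).
#' @return Numeric vector of points retained, one per participant.
#' @export
score_run <- function(log, config = log$config) {
  stopifnot(inherits(log, "run_log"))
  if (!identical(log$run_id, config$run_id)) stop("run_id mismatch")
  100 - config$loss[cbind(log$final_state, log$outcome)]
}

#' Generate a full synthetic experiment
#'
#' Maps [simulate_run()] over a design with per-run seeds derived from the
#' master seed, so the whole experiment is reproducible from `(design, seed)`.
#'
#' @param design list of `run_config`s from [make_design()].
#' @param model an [evac_model()].
#' @param seed integer master seed; run i uses `seed * 1000 + i` reduced
#'   modulo 2^31 - 1.
#' @return A list of `run_log`s with a `manifest` attribute (data frame of
#'   run ids, seeds, capacities, regimes, outcomes, end times).
#' @export
generate_experiment <- function(design, model, seed = 1L) {
  seeds <- (as.numeric(seed) * 1000 + seq_along(design)) %% (2^31 - 1)
  logs <- lapply(seq_along(design), function(i)
    simulate_run(design[[i]], model, seed = as.integer(seeds[i])))
  num <- function(field) vapply(logs, function(l) as.numeric(l[[field]]), numeric(1))
  manifest <- data.frame(
    run_id = num("run_id"),
    seed = as.integer(seeds),
    capacity = num("capacity"),
    regime = vapply(logs, `[[`, character(1), "regime"),
    outcome = vapply(logs, `[[`, character(1), "outcome"),
    end_time = num("end_time"))
  attr(logs, "manifest") <- manifest
  logs
}
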