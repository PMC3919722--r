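#' Write run logs to plain-text files
#'
#' Writes a tidy per-second CSV (`run_logs.csv`: run_id, t, participant,
#' state, evac_event, q_display, regime_window, beds_filled) and a JSON
#' manifest (`manifest.json`: schema version, per-run regime, outcome, end
#' time, capacity, seed, loss matrix).
#'
#' @param logs list of `run_log`s.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_run_logs <- function(logs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  panel <- do.call(rbind, lapply(logs, as.data.frame))
  utils::write.csv(panel, file.path(path, "run_logs.csv"), row.names = FALSE)
  runs <- lapply(logs, function(x) list(
    run_id = x$run_id, regime = x$regime, outcome = x$outcome,
    end_time = x$end_time, capacity = x$capacity, n_agents = x$n_agents,
    seed = x$seed, loss = as.data.frame(unclass(x$config$loss)),
    # start-of-interval states cannot distinguish a last-second evacuee's
    # destination, so final states and bed indices live in the manifest
    final_state = x$final_state, bed = x$bed,
    points = unname(score_run(x))))
  jsonlite::write_json(list(schema_version = 1L, runs = runs),
                       file.path(path, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read run logs back from disk
#'
#' Validates on read: known schema version, legal states, the indicator
#' conservation law (an agent leaves home exactly at its single evacuation
#' event and never returns), and shelter occupancy never exceeding
#' capacity. Violations are reported with the offending run and row.
#'
#' @param path directory written by [write_run_logs()].
#' @return A list of `run_log`s (empty, with a warning, if the directory
#'   holds no logs).
#' @export
read_run_logs <- function(path) {
  csv <- file.path(path, "run_logs.csv")
  mf <- file.path(path, "manifest.json")
  if (!file.exists(csv) || !file.exists(mf)) {
    warning("no run logs found in ", path)
    return(list())
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$schema_version) || manifest$schema_version != 1L)
    stop("unknown run-log schema version")
  panel <- utils::read.csv(csv)
  bad <- which(!panel$state %in% c("AtHome", "InTransit", "InShelter"))
  if (length(bad)) stop("illegal state at run_logs.csv row ", bad[1])
  runs <- manifest$runs
  lapply(seq_len(nrow(runs)), function(i) {
    meta <- runs[i, ]
    sub <- panel[panel$run_id == meta$run_id, , drop = FALSE]
    n <- meta$n_agents
    end_time <- meta$end_time
    evac_time <- rep(NA_integer_, n)
    final_state <- meta$final_state[[1]]
    bed <- suppressWarnings(as.integer(meta$bed[[1]]))
    for (p in seq_len(n)) {
      rows <- sub[sub$participant == p, , drop = FALSE]
      rows <- rows[order(rows$t), , drop = FALSE]
      ev <- which(rows$evac_event == 1L)
      if (length(ev) > 1L)
        stop(sprintf("run %s participant %d: multiple evacuation events",
                     meta$run_id, p))
      home <- rows$state == "AtHome"
      expected_home <- if (length(ev)) c(rep(TRUE, ev), rep(FALSE, end_time - ev))
                       else rep(TRUE, end_time)
      mismatch <- which(home != expected_home)
      if (length(mismatch))
        stop(sprintf("run %s participant %d t %d: state inconsistent with evacuation events",
                     meta$run_id, p, rows$t[mismatch[1]]))
      if (length(ev)) {
        evac_time[p] <- rows$t[ev]
        if (final_state[p] == "AtHome")
          stop(sprintf("run %s participant %d: evacuated but recorded AtHome",
                       meta$run_id, p))
      } else if (final_state[p] != "AtHome") {
        stop(sprintf("run %s participant %d: recorded %s without an evacuation event",
                     meta$run_id, p, final_state[p]))
      }
    }
    if (sum(final_state == "InShelter") > meta$capacity)
      stop(sprintf("run %s: sheltered count exceeds capacity %d",
                   meta$run_id, meta$capacity))
    lm <- meta$loss[[1]]
    loss <- loss_matrix(miss = lm$Miss, hit = lm$Hit)
    q_display <- sub$q_display[match(seq_len(end_time), sub$t)]
    traj <- structure(list(q_display = q_display, q_exact = q_display,
                           end_time = end_time, outcome = meta$outcome,
                           regime = meta$regime, config = NULL),
                      class = "threat_trajectory")
    config <- structure(list(run_id = meta$run_id, trajectory = traj,
                             capacity = meta$capacity, loss = loss,
                             network = NULL, n_agents = n,
                             node_assignment = seq_len(n)),
                        class = "run_config")
    at_home <- vapply(seq_len(end_time), function(t)
      sum(is.na(evac_time) | evac_time >= t), integer(1))
    structure(list(run_id = meta$run_id, n_agents = n, end_time = end_time,
                   outcome = meta$outcome, regime = meta$regime,
                   capacity = meta$capacity, evac_time = evac_time, bed = bed,
                   final_state = final_state, at_home = at_home,
                   config = config, seed = meta$seed),
              class = "run_log")
  })
}

#' Run the full analysis pipeline
#'
#' Drives the end-to-end chain: trajectory pool, nested design, synthetic
#' experiment, indicator aggregation, six-parameter fit, optional run-level
#' bootstrap and LOOCV, forward predictions, and the strict-threshold payoff
#' curve. Every stage derives its seed deterministically from the master
#' seed, so identical `(arguments, seed)` give identical output.
#'
#' @param seed master integer seed.
#' @param n_runs number of runs in the synthetic experiment.
#' @param model generating [evac_model()].
#' @param n_boot bootstrap replicates (0 skips the bootstrap with a warning).
#' @param do_loocv run leave-one-out cross-validation?
#' @param out_dir if non-`NULL`, logs and a JSON report are written here.
#' @return A report list: `fit` (the `evac_fit`), `coefficients`, `boot_sd`,
#'   `loocv` summary, `payoff` curve, `manifest`, `logs`.
#' @export
run_pipeline <- function(seed = 1L, n_runs = 47L, model = evac_model(),
                         n_boot = 0L, do_loocv = FALSE, out_dir = NULL) {
  pool <- trajectory_pool(seed = seed)
  design <- make_design(n_runs, trajectories = pool, seed = seed + 1L)
  logs <- generate_experiment(design, model, seed = seed + 2L)
  fit <- evac_fit(logs, model = "sixparam")
  boot <- NULL
  if (n_boot > 0L) {
    boot <- bootstrap_params(logs, model = "sixparam", n_boot = n_boot,
                             seed = seed + 3L)
    fit$boot_sd <- boot$sd
  } else {
    warning("n_boot = 0: parameter uncertainties not estimated")
  }
  cv <- if (do_loocv) loocv(logs, model = "sixparam") else NULL
  payoff <- strict_threshold_payoff(seq(0, 1, by = 0.1), design)
  report <- list(
    coefficients = coef(fit),
    logLik = fit$logLik,
    boot_sd = if (is.null(boot)) NULL else boot$sd,
    loocv = if (is.null(cv)) NULL else
      list(mean_abs_gap = cv$mean_abs_gap, relative_gap = cv$relative_gap),
    payoff = payoff,
    manifest = attr(logs, "manifest"))
  if (!is.null(out_dir)) {
    write_run_logs(logs, out_dir)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  c(report, list(fit = fit, logs = logs))
}
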