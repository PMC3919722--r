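#' Parameter recovery study
#'
#' Generates repeated synthetic experiments from a known six-parameter
#' decision model -- crossing shelter capacities \{10..50\} and both time
#' regimes over a fresh trajectory pool per repetition -- refits the
#' six-parameter model to each, and summarizes how well each generating
#' parameter is recovered. This is the package's main self-validation:
#' because the laboratory's raw logs were never deposited, the reference
#' parameter vector is used as generating truth and the estimator is judged
#' by its ability to recover it.
#'
#' @param n_reps number of seeded repetitions.
#' @param n_runs runs per repetition (50 agents each).
#' @param truth generating [evac_model()].
#' @param seed integer master seed.
#' @param control optimizer control passed to [evac_fit()].
#' @return An object of class `recovery_study`: `replicates` (data frame of
#'   recovered parameters, one row per repetition), `mean` (named vector of
#'   mean recovered values), `truth`.
#' @export
recovery_study <- function(n_reps = 20L, n_runs = 188L, truth = evac_model(),
                           seed = 1L, control = list()) {
  par_names <- c("h", "r_T1", "r_T2", "r_T3", "theta0", "c")
  reps <- matrix(NA_real_, n_reps, length(par_names),
                 dimnames = list(NULL, par_names))
  for (rep in seq_len(n_reps)) {
    rs <- as.integer((as.numeric(seed) * 10000 + rep * 97) %% (2^31 - 1))
    pool <- trajectory_pool(23L, seed = rs)
    design <- make_design(n_runs, trajectories = pool, seed = rs + 1L)
    logs <- generate_experiment(design, truth, seed = rs + 2L)
    fit <- evac_fit(logs, model = "sixparam", control = control)
    reps[rep, ] <- coef(fit)[par_names]
  }
  structure(list(replicates = as.data.frame(reps),
                 mean = colMeans(reps),
                 truth = coef(truth)[par_names],
                 n_reps = n_reps, n_runs = n_runs, seed = seed),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d repetitions of %d runs x 50 agents\n",
              x$n_reps, x$n_runs))
  tab <- data.frame(truth = x$truth, mean_recovered = x$mean,
                    rel_error = x$mean / x$truth - 1)
  print(round(tab, 4))
  invisible(x)
}
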