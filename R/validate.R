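#' Bootstrap parameter uncertainties
#'
#' Resamples whole runs with replacement (47 runs drawn from 47, as many
#' times as requested), re-aggregates the counts, refits the model, and
#' reports the standard deviation of each parameter over replicates --
#' the run-level bootstrap used for all reported parameter uncertainties.
#'
#' @param logs list of `run_log`s.
#' @param model fit family passed to [evac_fit()].
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param control optimizer control passed to [evac_fit()].
#' @return An object of class `evac_boot`: `sd` (named vector), `replicates`
#'   (matrix, one row per replicate), `n_degenerate`.
#' @export
bootstrap_params <- function(logs, model = "sixparam", n_boot = 100L,
                             seed = 1L, control = list()) {
  if (n_boot < 2L) stop("`n_boot` must be >= 2")
  set.seed(seed)
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    take <- sample.int(length(logs), replace = TRUE)
    fit <- tryCatch(evac_fit(logs[take], model = model, control = control),
                    error = function(e) NULL)
    reps[[b]] <- if (is.null(fit)) NULL else
      list(par = coef(fit), degenerate = fit$degenerate)
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok)) stop("all bootstrap replicates failed to fit")
  mat <- do.call(rbind, lapply(reps[ok], `[[`, "par"))
  n_deg <- sum(vapply(reps[ok], `[[`, logical(1), "degenerate"))
  if (n_deg == sum(ok))
    warning("all bootstrap replicates flagged degenerate")
  structure(list(sd = apply(mat, 2, stats::sd), replicates = mat,
                 n_boot = n_boot, n_fitted = sum(ok), n_degenerate = n_deg),
            class = "evac_boot")
}

#' @export
print.evac_boot <- function(x, ...) {
  cat(sprintf("Run-level bootstrap, %d/%d replicates fitted\n",
              x$n_fitted, x$n_boot))
  print(round(x$sd, 5))
  invisible(x)
}

#' Leave-one-out cross-validation of predicted evacuation curves
#'
#' For each run, refits the model on the remaining runs and forward-predicts
#' the held-out run's expected at-home curve; the same curve from the
#' full-data fit gauges overfitting -- for a well-specified model the two
#' are nearly identical.
#'
#' @param logs list of `run_log`s (>= 2).
#' @param model fit family.
#' @param control optimizer control passed to [evac_fit()].
#' @return An object of class `evac_loocv`: per-run data frames of held-out
#'   and full-model curves, the mean absolute gap between them, and that gap
#'   relative to the mean within-run curve range.
#' @export
loocv <- function(logs, model = "sixparam", control = list()) {
  if (length(logs) < 2L) stop("LOOCV needs at least 2 runs")
  full <- evac_fit(logs, model = model, control = control)
  full_model <- as_evac_model(full)
  curves <- lapply(seq_along(logs), function(i) {
    held <- evac_fit(logs[-i], model = model, control = control)
    cfg <- logs[[i]]$config
    data.frame(run_id = logs[[i]]$run_id,
               t = 0:logs[[i]]$end_time,
               full = expected_at_home(full_model, cfg)$at_home,
               heldout = expected_at_home(as_evac_model(held), cfg)$at_home,
               observed = observed_at_home(logs[[i]]))
  })
  gaps <- vapply(curves, function(d) mean(abs(d$full - d$heldout)), numeric(1))
  ranges <- vapply(curves, function(d) diff(range(d$full)), numeric(1))
  structure(list(curves = curves, full_fit = full,
                 mean_abs_gap = mean(gaps),
                 relative_gap = mean(gaps) / max(mean(ranges), 1e-12)),
            class = "evac_loocv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.evac_loocv <- function(x, ...) {
  cat(sprintf("LOOCV over %d runs: mean |held-out - full| = %.3f agents (%.1f%% of mean curve range)\n",
              length(x$curves), x$mean_abs_gap, 100 * x$relative_gap))
  invisible(x)
}

#' Per-participant decision-model fits
#'
#' Fits the three-parameter Hill law to each participant's own rate curve
#' (counts partitioned by displayed likelihood and participant). Sparse
#' individual data makes some fits degenerate (e.g. participants who never
#' evacuate); these are flagged, not dropped.
#'
#' @param logs list of `run_log`s.
#' @param control optimizer control passed to [evac_fit()].
#' @return A list with `fits` (per-participant `evac_fit` or `NULL`),
#'   `params` (data frame: participant, r_max, theta, h, degenerate), and
#'   `scores` (cumulative points per participant over the runs).
#' @export
fit_individuals <- function(logs, control = list()) {
  panel <- build_indicators(logs)
  cells <- aggregate_counts(panel, "by_q_individual")
  scores <- Reduce(`+`, lapply(logs, score_run))
  ids <- sort(unique(cells$participant))
  fits <- lapply(ids, function(p) {
    sub <- cells[cells$participant == p, , drop = FALSE]
    class(sub) <- class(cells)
    tryCatch(evac_fit(sub, model = "hill", control = control),
             error = function(e) NULL)
  })
  params <- data.frame(
    participant = ids,
    r_max = vapply(fits, function(f) if (is.null(f)) NA_real_ else coef(f)[["r_max"]], numeric(1)),
    theta = vapply(fits, function(f) if (is.null(f)) NA_real_ else coef(f)[["theta"]], numeric(1)),
    h = vapply(fits, function(f) if (is.null(f)) NA_real_ else coef(f)[["h"]], numeric(1)),
    degenerate = vapply(fits, function(f) is.null(f) || f$degenerate, logical(1)),
    score = scores[ids])
  list(fits = fits, params = params, scores = scores)
}

#' Correlate fitted parameters with performance
#'
#' Pearson correlations (two-sided p-values, no multiplicity correction;
#' exploratory usage) between per-participant parameter estimates and any
#' participant-level covariate, typically the cumulative score.
#'
#' @param params data frame from [fit_individuals()]`$params`.
#' @param covariate numeric vector aligned with `params$participant`
#'   (defaults to `params$score`).
#' @param vars parameter columns to test.
#' @return Data frame with columns `parameter`, `r`, `p_value`, `n`.
#' @export
score_correlations <- function(params, covariate = params$score,
                               vars = c("r_max", "theta", "h")) {
  out <- lapply(vars, function(v) {
    ok <- is.finite(params[[v]]) & is.finite(covariate)
    ct <- stats::cor.test(params[[v]][ok], covariate[ok])
    data.frame(parameter = v, r = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok))
  })
  do.call(rbind, out)
}
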