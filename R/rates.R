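#' Build the indicator panel from run logs
#'
#' For every (participant i, interval t, run r) triple, the at-home
#' indicator `H` is 1 if the participant was AtHome at the start of the
#' interval and the event indicator `E` is 1 if they evacuated during it.
#' The two satisfy the conservation law `H[i, t+1] = H[i, t] - E[i, t]`,
#' which is re-verified here; intervals after a run's end contribute
#' nothing.
#'
#' @param logs a list of `run_log`s.
#' @return A data frame with columns `run_id`, `t`, `participant`, `H`, `E`,
#'   `q_display`, `capacity`, `window`, `regime`.
#' @export
build_indicators <- function(logs) {
  if (inherits(logs, "run_log")) logs <- list(logs)
  pieces <- lapply(logs, function(x) {
    stopifnot(inherits(x, "run_log"))
    tt <- rep(seq_len(x$end_time), each = x$n_agents)
    pid <- rep(seq_len(x$n_agents), times = x$end_time)
    ev <- x$evac_time[pid]
    H <- as.integer(is.na(ev) | ev >= tt)
    E <- as.integer(!is.na(ev) & ev == tt)
    if (any(E == 1L & H == 0L))
      stop(sprintf("run %s: evacuation event by a participant not AtHome", x$run_id))
    # conservation across consecutive intervals
    hm <- matrix(H, nrow = x$n_agents)
    em <- matrix(E, nrow = x$n_agents)
    if (x$end_time > 1L &&
        any(hm[, -1L] != hm[, -x$end_time] - em[, -x$end_time]))
      stop(sprintf("run %s: indicator conservation violated", x$run_id))
    data.frame(run_id = x$run_id, t = tt, participant = pid, H = H, E = E,
               q_display = x$config$trajectory$q_display[tt],
               capacity = x$capacity,
               window = time_window(tt, x$regime), regime = x$regime)
  })
  do.call(rbind, pieces)
}

#' Aggregate indicators into partition-cell counts
#'
#' Pools the at-home seconds (`n = sum H`) and evacuation events
#' (`m = sum E`) over a partition of the observations: by displayed
#' likelihood alone (11 cells), by likelihood and shelter capacity
#' (up to 55), by likelihood, capacity, and time-urgency window (up to 165),
#' or by likelihood and participant.
#'
#' @param panel indicator panel from [build_indicators()].
#' @param scheme one of `"by_q"`, `"by_q_B"`, `"by_q_B_T"`,
#'   `"by_q_individual"`.
#' @param drop_empty drop cells never observed (`n = 0`)? Unobserved cells
#'   carry only the prior and are excluded from fitting.
#' @return A data frame of class `rate_cells` with the partition keys plus
#'   `n`, `m`, `R`, `sd`, and `unobserved`; `R` and `sd` are the Beta
#'   posterior mean and standard deviation from [beta_rate()].
#' @export
aggregate_counts <- function(panel,
                             scheme = c("by_q", "by_q_B", "by_q_B_T",
                                        "by_q_individual"),
                             drop_empty = TRUE) {
  scheme <- match.arg(scheme)
  q_levels <- seq(0, 1, by = 0.1)
  keys <- list(q = factor(round(panel$q_display, 1), levels = q_levels))
  if (scheme %in% c("by_q_B", "by_q_B_T"))
    keys$capacity <- factor(panel$capacity)
  if (scheme == "by_q_B_T")
    keys$window <- factor(panel$window, levels = c("T1", "T2", "T3"))
  if (scheme == "by_q_individual")
    keys$participant <- factor(panel$participant)
  grid <- expand.grid(lapply(keys, levels), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  lev <- do.call(paste, c(grid, sep = "\r"))
  f <- factor(do.call(paste, c(lapply(keys, as.character), sep = "\r")),
              levels = lev)
  n <- as.vector(tapply(panel$H, f, sum, default = 0))
  m <- as.vector(tapply(panel$E, f, sum, default = 0))
  est <- beta_rate(m, n)
  out <- cbind(grid, n = n, m = m, R = est$R, sd = est$sd,
               unobserved = n == 0)
  out$q <- as.numeric(as.character(out$q))
  if (!is.null(out$capacity))
    out$capacity <- as.numeric(as.character(out$capacity))
  if (!is.null(out$window)) out$window <- as.character(out$window)
  if (!is.null(out$participant))
    out$participant <- as.integer(as.character(out$participant))
  if (drop_empty) out <- out[!out$unobserved, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  class(out) <- c("rate_cells", "data.frame")
  out
}

#' Rate table straight from logs
#'
#' Convenience wrapper: [build_indicators()] then [aggregate_counts()].
#'
#' @inheritParams aggregate_counts
#' @param logs list of `run_log`s.
#' @export
rate_table <- function(logs, scheme = "by_q_B_T", drop_empty = TRUE) {
  aggregate_counts(build_indicators(logs), scheme, drop_empty)
}

#' Beta-posterior rate estimate
#'
#' Treating each at-home second as a Bernoulli trial, the likelihood of the
#' underlying per-second rate given `m` evacuations in `n` exposures is
#' Beta(m + 1, n - m + 1). The measured rate is its mean
#' `(m + 1) / (n + 2)`, and the uncertainty its standard deviation
#' `sqrt((m + 1) (n - m + 1) / ((n + 2)^2 (n + 3)))`. With abundant data the
#' estimate converges to the naive fraction `m / n`; with none it returns
#' the uniform-prior mean 0.5.
#'
#' @param m evacuation counts (0 <= m <= n).
#' @param n exposure counts.
#' @return A list with components `R` and `sd`, vectorised over the inputs.
#' @examples
#' beta_rate(0, 0)   # prior: R = 0.5, sd = sqrt(1/12)
#' beta_rate(3, 10)  # R = 4/12
#' @export
beta_rate <- function(m, n) {
  if (any(m < 0) || any(n < 0)) stop("counts must be >= 0")
  if (any(m > n)) stop("`m` cannot exceed `n`")
  R <- (m + 1) / (n + 2)
  sd <- sqrt((m + 1) * (n - m + 1) / ((n + 2)^2 * (n + 3)))
  list(R = R, sd = sd)
}
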