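# Shared fixtures, built in code at load time. Small on purpose: the heavy
# simulations live in the tests that need them.

# Exhaustive-path oracle for the strike likelihood: enumerate every lateral
# step sequence (and, for VariableTime, every forward step sequence) and
# average the hit indicator. Tractable for horizon <= 6, volatility <= 2.
enum_hit_prob <- function(x, f, config) {
  if (f == 0) return(as.numeric(abs(x) <= config$halfwidth))
  v <- config$volatility
  p2 <- config$p_fast
  steps <- -v:v
  tot <- 0
  for (l in steps) {
    slow <- enum_hit_prob(x + l, max(f - 1, 0), config)
    if (p2 > 0) {
      fast <- enum_hit_prob(x + l, max(f - 2, 0), config)
      tot <- tot + ((1 - p2) * slow + p2 * fast)
    } else {
      tot <- tot + slow
    }
  }
  tot / length(steps)
}

# Hand-built deterministic trajectory whose display level climbs to 0.9
# before a CertainTime hit.
fixture_rising_trajectory <- function() {
  q <- c(rep(0.2, 20), rep(0.4, 15), rep(0.6, 10), rep(0.8, 10), rep(0.9, 5))
  threat_trajectory(q, regime = "CertainTime", outcome = "Hit")
}

fixture_run_config <- function(capacity = 50L, n_agents = 50L,
                               trajectory = fixture_rising_trajectory()) {
  run_config(trajectory, capacity = capacity, n_agents = n_agents)
}

# A small but informative synthetic experiment shared by estimation tests.
fixture_logs <- local({
  value <- NULL
  function(n_runs = 47L, seed = 101L) {
    key <- paste(n_runs, seed)
    if (is.null(value) || attr(value, "key") != key) {
      pool <- trajectory_pool(23L, seed = seed)
      design <- make_design(n_runs, trajectories = pool, seed = seed + 1L)
      logs <- generate_experiment(design, evac_model(), seed = seed + 2L)
      attr(logs, "key") <- key
      value <<- logs
    }
    value
  }
})

# Noiseless cells: expected counts from a known law, rounded from huge
# exposures, so the count MLE must land on the generating parameters.
noiseless_hill_cells <- function(r_max, theta, h, n_per_cell = 1e7) {
  q <- seq(0, 1, by = 0.1)
  r <- hill_rate(q, r_max, theta, h)
  cells <- data.frame(q = q, n = rep(n_per_cell, length(q)),
                      m = round(r * n_per_cell))
  est <- beta_rate(cells$m, cells$n)
  cells$R <- est$R; cells$sd <- est$sd; cells$unobserved <- FALSE
  class(cells) <- c("rate_cells", "data.frame")
  cells
}
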