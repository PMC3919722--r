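# a slimmed optimizer start set keeps the many refits in these tests cheap
fast_ctrl <- list(starts = list(
  c(h = 9, r_T1 = 0.1, r_T2 = 0.3, r_T3 = 0.1, theta0 = 0.6, c = 0),
  c(h = 3, r_T1 = 0.05, r_T2 = 0.05, r_T3 = 0.05, theta0 = 0.4, c = 0),
  c(h = 15, r_T1 = 0.3, r_T2 = 0.3, r_T3 = 0.3, theta0 = 0.75, c = 0)))

test_that("bootstrap SDs are seeded, deterministic, and zero for one run", {
  logs <- fixture_logs()
  b1 <- bootstrap_params(logs, n_boot = 8, seed = 5, control = fast_ctrl)
  b2 <- bootstrap_params(logs, n_boot = 8, seed = 5, control = fast_ctrl)
  expect_identical(b1$sd, b2$sd)
  expect_true(all(b1$sd >= 0))
  expect_named(b1$sd, c("h", "r_T1", "r_T2", "r_T3", "theta0", "c"))
  expect_error(bootstrap_params(logs, n_boot = 1), ">= 2")
})

test_that("bootstrap uncertainty shrinks roughly like sqrt(n) in runs", {
  small <- fixture_logs()                       # 47 runs
  pool <- trajectory_pool(23L, seed = 101L)
  design <- make_design(188L, trajectories = pool, seed = 102L)
  big <- generate_experiment(design, evac_model(), seed = 103L)  # 4x runs
  bs <- bootstrap_params(small, n_boot = 12, seed = 9, control = fast_ctrl)
  bb <- bootstrap_params(big, n_boot = 12, seed = 9, control = fast_ctrl)
  # 4x the runs should halve the SD, within a factor of 2 either way
  for (p in c("r_T2", "theta0")) {
    ratio <- bs$sd[[p]] / bb$sd[[p]]
    expect_gt(ratio, 1)
    expect_lt(ratio, 8)
  }
})

test_that("LOOCV folds train on the complement and handle 2-run input", {
  logs <- fixture_logs()[1:2]
  # each fold trains on a single run, so only the pooled hill law is fittable
  cv <- loocv(logs, model = "hill")
  expect_length(cv$curves, 2L)
  expect_equal(cv$curves[[1]]$t[1], 0)
  expect_equal(cv$curves[[1]]$full[1], 50)
  expect_error(loocv(fixture_logs()[1]), "at least 2")
})

test_that("LOOCV flags a grossly misspecified generator", {
  # every run generated from a wildly different decision law: the held-out
  # prediction must err more than the full-model prediction
  pool <- trajectory_pool(8L, seed = 61)
  design <- make_design(8L, trajectories = pool, seed = 62)
  set.seed(63)
  logs <- lapply(seq_along(design), function(i) {
    m <- evac_model(h = sample(c(1, 30), 1),
                    r_T1 = stats::runif(1, 0.01, 0.9),
                    r_T2 = stats::runif(1, 0.01, 0.9),
                    r_T3 = stats::runif(1, 0.01, 0.9),
                    theta0 = stats::runif(1, 0.2, 0.8), c = 0)
    simulate_run(design[[i]], m, seed = 63 + i)
  })
  cv <- loocv(logs, control = fast_ctrl)
  err <- function(col) mean(vapply(cv$curves, function(d)
    sqrt(mean((d$observed - d[[col]])^2)), numeric(1)))
  expect_gt(err("heldout"), err("full"))
})

test_that("individual fits recover heterogeneous rates and flag flat-liners", {
  pool <- trajectory_pool(23L, seed = 71)
  design <- make_design(60L, trajectories = pool, n_agents = 12L,
                        capacities = 12L, seed = 72)
  # 12 agents with increasing maximum rates; agent 1 never evacuates
  r_true <- c(1e-9, seq(0.05, 0.6, length.out = 11))
  set.seed(73)
  logs <- lapply(design, function(cfg) {
    traj <- cfg$trajectory
    windows <- time_window(seq_len(traj$end_time), traj$regime)
    ev <- rep(NA_integer_, 12L)
    for (a in 1:12) {
      r <- pmin(hill_rate(pmax(traj$q_display, 1e-12), max(r_true[a], 1e-9),
                          0.6, 9), 1)
      u <- stats::runif(traj$end_time)
      hit_t <- which(u < r)
      if (length(hit_t)) ev[a] <- hit_t[1]
    }
    at_home <- vapply(seq_len(traj$end_time), function(t)
      sum(is.na(ev) | ev >= t), integer(1))
    structure(list(run_id = cfg$run_id, n_agents = 12L,
                   end_time = traj$end_time, outcome = traj$outcome,
                   regime = traj$regime, capacity = 12L, evac_time = ev,
                   bed = ifelse(is.na(ev), NA_integer_, 1L),
                   final_state = ifelse(is.na(ev), "AtHome", "InShelter"),
                   at_home = at_home, config = cfg, seed = NULL),
              class = "run_log")
  })
  ind <- fit_individuals(logs)
  expect_equal(nrow(ind$params), 12L)
  expect_true(ind$params$degenerate[1])  # the never-evacuator
  ok <- !ind$params$degenerate
  expect_gt(stats::cor(r_true[ok], ind$params$r_max[ok], method = "spearman"),
            0.7)
  cors <- score_correlations(ind$params)
  expect_named(cors, c("parameter", "r", "p_value", "n"))
  expect_true(all(cors$p_value >= 0 & cors$p_value <= 1))
})
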