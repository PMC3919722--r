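test_that("beta_rate matches its closed forms and numerical Beta moments", {
  pr <- beta_rate(0, 0)
  expect_equal(pr$R, 0.5)
  expect_equal(pr$sd, sqrt(1 / 12))
  est <- beta_rate(3, 10)
  expect_equal(est$R, 4 / 12)
  expect_equal(est$sd, sqrt(32 / 1872))
  # oracle: moments of Beta(m+1, n-m+1) by numerical integration
  for (m in c(0, 1, 7, 50)) for (n in c(m, m + 3, m + 200)) {
    mean_num <- stats::integrate(function(x) x * stats::dbeta(x, m + 1, n - m + 1),
                                 0, 1, rel.tol = 1e-12)$value
    m2 <- stats::integrate(function(x) x^2 * stats::dbeta(x, m + 1, n - m + 1),
                           0, 1, rel.tol = 1e-12)$value
    got <- beta_rate(m, n)
    expect_equal(got$R, mean_num, tolerance = 1e-10)
    expect_equal(got$sd, sqrt(m2 - mean_num^2), tolerance = 1e-10)
  }
  expect_error(beta_rate(5, 3), "exceed")
})

test_that("beta_rate is monotone in counts", {
  n <- 40
  R <- beta_rate(0:n, n)$R
  expect_true(all(diff(R) > 0))
  # sd shrinks as n grows at fixed m/n
  sds <- vapply(c(10, 40, 160, 640), function(k) beta_rate(k / 2, k)$sd,
                numeric(1))
  expect_true(all(diff(sds) < 0))
  # m = n estimates approach 1 from below
  Rn <- vapply(c(10, 100, 1000), function(k) beta_rate(k, k)$R, numeric(1))
  expect_true(all(diff(Rn) > 0) && all(Rn < 1))
})

test_that("indicators reconstruct evacuation histories", {
  tr <- threat_trajectory(c(rep(0.3, 40), rep(0.6, 20)), "CertainTime", "Miss")
  cfg <- run_config(tr, n_agents = 2L, capacity = 2L, run_id = 9L)
  log <- structure(list(run_id = 9L, n_agents = 2L, end_time = 60L,
                        outcome = "Miss", regime = "CertainTime", capacity = 2L,
                        evac_time = c(12L, NA), bed = c(1L, NA),
                        final_state = c("InShelter", "AtHome"),
                        at_home = c(rep(2L, 12), rep(1L, 48)),
                        config = cfg, seed = NULL),
                   class = "run_log")
  panel <- build_indicators(log)
  p1 <- panel[panel$participant == 1, ]
  expect_equal(p1$H, c(rep(1L, 12), rep(0L, 48)))
  expect_equal(which(p1$E == 1L), 12L)
  p2 <- panel[panel$participant == 2, ]
  expect_equal(sum(p2$H), 60L)  # never evacuates: 60 exposure seconds
  expect_equal(sum(p2$E), 0L)
})

test_that("a hand-enumerated toy log aggregates to the right cell counts", {
  # two participants; only second 41 shows q = 0.6, where one evacuates
  q <- c(rep(0.3, 40), 0.6, rep(0.4, 19))
  tr <- threat_trajectory(q, "CertainTime", "Miss")
  cfg <- run_config(tr, n_agents = 2L, capacity = 2L)
  log <- structure(list(run_id = 1L, n_agents = 2L, end_time = 60L,
                        outcome = "Miss", regime = "CertainTime", capacity = 2L,
                        evac_time = c(41L, NA), bed = c(1L, NA),
                        final_state = c("InShelter", "AtHome"),
                        at_home = c(rep(2L, 41), rep(1L, 19)),
                        config = cfg, seed = NULL),
                   class = "run_log")
  cells <- rate_table(list(log), "by_q")
  cell6 <- cells[cells$q == 0.6, ]
  expect_equal(cell6$n, 2)
  expect_equal(cell6$m, 1)
  expect_equal(cell6$R, 2 / 4)
})

test_that("refining a partition and summing back reproduces the counts", {
  logs <- fixture_logs()
  panel <- build_indicators(logs)
  by_q <- aggregate_counts(panel, "by_q", drop_empty = FALSE)
  by_qb <- aggregate_counts(panel, "by_q_B", drop_empty = FALSE)
  by_qbt <- aggregate_counts(panel, "by_q_B_T", drop_empty = FALSE)
  expect_equal(tapply(by_qb$n, by_qb$q, sum), tapply(by_q$n, by_q$q, sum))
  expect_equal(tapply(by_qbt$m, by_qbt$q, sum), tapply(by_q$m, by_q$q, sum))
  expect_equal(sum(by_q$n), sum(panel$H))
  expect_equal(sum(by_q$m), sum(panel$E))
  # per-run conservation: exposure equals the at-home headcount summed over t
  one <- build_indicators(logs[[1]])
  expect_equal(sum(aggregate_counts(one, "by_q")$n), sum(logs[[1]]$at_home))
})

test_that("empty panels yield all-prior cells flagged unobserved", {
  panel <- build_indicators(fixture_logs()[1])[0, ]
  cells <- aggregate_counts(panel, "by_q", drop_empty = FALSE)
  expect_equal(nrow(cells), 11L)
  expect_true(all(cells$unobserved))
  expect_true(all(cells$R == 0.5))
  expect_equal(nrow(aggregate_counts(panel, "by_q")), 0L)
})

test_that("cell estimates cover a constant generating rate", {
  # hand-built logs where every at-home second is Bernoulli(r) regardless
  # of q: >= 90% of by_q cells must cover r within 2 sd
  r <- 0.04
  q <- rep(seq(0, 0.9, by = 0.1), 6)  # visits 10 levels every run
  tr <- threat_trajectory(q, "CertainTime", "Miss")
  set.seed(23)
  logs <- lapply(1:40, function(i) {
    ev <- stats::rgeom(50, r) + 1L
    ev[ev > 60L] <- NA_integer_
    at_home <- vapply(1:60, function(t) sum(is.na(ev) | ev >= t), integer(1))
    structure(list(run_id = i, n_agents = 50L, end_time = 60L,
                   outcome = "Miss", regime = "CertainTime", capacity = 50L,
                   evac_time = ev, bed = ifelse(is.na(ev), NA_integer_, 1L),
                   final_state = ifelse(is.na(ev), "AtHome", "InShelter"),
                   at_home = at_home,
                   config = run_config(tr, run_id = i), seed = NULL),
              class = "run_log")
  })
  cells <- rate_table(logs, "by_q")
  covered <- abs(cells$R - r) <= 2 * cells$sd
  expect_gte(mean(covered), 0.9)
})
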