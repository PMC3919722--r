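test_that("the Hill law hits its half-maximum at the threshold", {
  set.seed(31)
  for (i in 1:1000) {
    r_max <- stats::runif(1, 0.01, 1)
    theta <- stats::runif(1, 0.05, 0.95)
    h <- stats::runif(1, 0.5, 40)
    expect_equal(hill_rate(theta, r_max, theta, h), r_max / 2)
  }
  expect_equal(hill_rate(0, 0.37, 0.7, 9.3), 0)
  expect_equal(hill_rate(1, 0.37, 0.7, 9.3), 0.37 / (1 + 0.7^9.3),
               tolerance = 1e-12)
  expect_equal(hill_rate(1, 0.37, 0.7, 9.3), 0.357, tolerance = 1e-3)
})

test_that("the count likelihood is additive and maximized at m/n", {
  cells <- data.frame(q = c(0.5, 0.7), n = c(100, 40), m = c(5, 10))
  ll <- count_log_likelihood(c(0.05, 0.25), cells)
  twice <- count_log_likelihood(c(0.05, 0.25, 0.05, 0.25),
                                rbind(cells, cells))
  expect_equal(twice, 2 * ll)
  # scalar-rate argmax for a single cell is the binomial MLE m/n
  one <- data.frame(q = 0.5, n = 40, m = 10)
  opt <- stats::optimize(function(r) count_log_likelihood(r, one),
                         c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, 10 / 40, tolerance = 1e-6)
  # m = n pushes the optimum to the upper boundary
  sat <- data.frame(q = 0.5, n = 20, m = 20)
  grid <- seq(0.05, 0.95, by = 0.05)
  lls <- vapply(grid, function(r) count_log_likelihood(r, sat), numeric(1))
  expect_true(all(diff(lls) > 0))
  expect_error(count_log_likelihood(0.1, data.frame(q = 0, n = 0, m = 0)),
               "excluded")
})

test_that("fit_hill recovers generating parameters from noiseless counts", {
  cells <- noiseless_hill_cells(r_max = 0.25, theta = 0.65, h = 8)
  fit <- evac_fit(cells, model = "hill")
  expect_equal(unname(coef(fit)), c(0.25, 0.65, 8),
               tolerance = 1e-3)
  expect_false(fit$degenerate)
  expect_s3_class(summary(fit), "summary.evac_fit")
})

test_that("all-zero counts produce a degenerate flagged fit", {
  cells <- noiseless_hill_cells(0.3, 0.6, 9)
  cells$m <- 0
  est <- beta_rate(cells$m, cells$n); cells$R <- est$R; cells$sd <- est$sd
  fit <- evac_fit(cells, model = "hill")
  expect_true(fit$degenerate)
  expect_lte(coef(fit)[["r_max"]], 1e-4 * 1.01)
})

test_that("the fit optimum agrees with a brute-force grid search", {
  # 10 small noisy cell sets; the MLE must lie within one grid cell of the
  # exhaustive coarse-grid optimum
  grid <- expand.grid(r_max = seq(0.05, 0.95, by = 0.1),
                      theta = seq(0.1, 0.9, by = 0.1),
                      h = c(1, 2, 4, 8, 16, 32))
  set.seed(42)
  for (rep in 1:10) {
    true <- list(r = stats::runif(1, 0.1, 0.6), th = stats::runif(1, 0.3, 0.8),
                 h = stats::runif(1, 3, 15))
    q <- seq(0, 1, by = 0.1)
    n <- rpois(11, 400) + 50
    m <- rbinom(11, n, hill_rate(q, true$r, true$th, true$h))
    cells <- data.frame(q = q, n = n, m = m)
    est <- beta_rate(m, n); cells$R <- est$R; cells$sd <- est$sd
    class(cells) <- c("rate_cells", "data.frame")
    lls <- vapply(seq_len(nrow(grid)), function(i)
      count_log_likelihood(hill_rate(q, grid$r_max[i], grid$theta[i],
                                     grid$h[i]), cells), numeric(1))
    gbest <- grid[which.max(lls), ]
    fit <- evac_fit(cells, model = "hill")
    expect_lte(abs(coef(fit)[["r_max"]] - gbest$r_max), 0.1)
    expect_lte(abs(coef(fit)[["theta"]] - gbest$theta), 0.1)
    # h grid is geometric (factor 2): the MLE must fall within one rung
    expect_lte(abs(log2(coef(fit)[["h"]]) - log2(gbest$h)), 1)
    # and never below the grid optimum's likelihood
    expect_gte(fit$logLik, max(lls) - 1e-6)
  }
})

test_that("capacity-linear threshold fits recover slope sign and null", {
  q <- seq(0, 1, by = 0.1)
  caps <- c(10, 20, 30, 40, 50)
  build <- function(theta0, c0, r_max = 0.3, h = 9, n_per = 1e7) {
    cells <- do.call(rbind, lapply(caps, function(B) {
      r <- hill_rate(q, r_max, theta0 + c0 * B, h)
      data.frame(q = q, capacity = B, n = n_per, m = round(r * n_per))
    }))
    est <- beta_rate(cells$m, cells$n); cells$R <- est$R; cells$sd <- est$sd
    class(cells) <- c("rate_cells", "data.frame")
    cells
  }
  # noiseless recovery
  fit <- evac_fit(build(0.55, 0.003), model = "capacity")
  expect_equal(coef(fit)[["theta0"]], 0.55, tolerance = 1e-3)
  expect_equal(coef(fit)[["c"]], 0.003, tolerance = 1e-4)
  # positive slope: fitted threshold at B=10 below that at B=50
  expect_lt(coef(fit)[["theta0"]] + 10 * coef(fit)[["c"]],
            coef(fit)[["theta0"]] + 50 * coef(fit)[["c"]])
  # null slope recovered as (near) zero
  fit0 <- evac_fit(build(0.6, 0), model = "capacity")
  expect_lt(abs(coef(fit0)[["c"]]), 1e-4)
  # single capacity level is redirected to the hill family
  one <- build(0.6, 0)
  one <- one[one$capacity == 30, ]
  class(one) <- c("rate_cells", "data.frame")
  expect_error(evac_fit(one, model = "capacity"), "hill")
})

test_that("six-parameter fits respect model nesting and window ordering", {
  logs <- fixture_logs()
  panel <- build_indicators(logs)
  f_hill <- evac_fit(aggregate_counts(panel, "by_q"), model = "hill")
  f_cap <- evac_fit(aggregate_counts(panel, "by_q_B"), model = "capacity")
  f_six <- evac_fit(aggregate_counts(panel, "by_q_B_T"), model = "sixparam")
  # likelihood can only improve as the model nests upward
  expect_gte(f_cap$logLik, f_hill$logLik - 1e-6)
  expect_gte(f_six$logLik, f_cap$logLik - 1e-6)
  # time-urgency ordering of the generating law is recovered
  co <- coef(f_six)
  expect_gt(co[["r_T2"]], co[["r_T3"]])
  expect_gt(co[["r_T3"]], co[["r_T1"]])
  # pooled threshold sits between the extreme capacity-specific thresholds
  th10 <- co[["theta0"]] + 10 * co[["c"]]
  th50 <- co[["theta0"]] + 50 * co[["c"]]
  expect_gt(coef(f_hill)[["theta"]], min(th10, th50) - 0.05)
  expect_lt(coef(f_hill)[["theta"]], max(th10, th50) + 0.05)
  # missing window errors
  sub <- f_six$cells[f_six$cells$window != "T1", ]
  class(sub) <- class(f_six$cells)
  expect_error(evac_fit(sub, model = "sixparam"), "window")
})

test_that("the argmax is invariant under duplicating every cell", {
  cells <- noiseless_hill_cells(0.3, 0.6, 9, n_per_cell = 1e5)
  doubled <- rbind(cells, cells)
  class(doubled) <- class(cells)
  f1 <- evac_fit(cells, model = "hill")
  f2 <- evac_fit(doubled, model = "hill")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
  expect_equal(f2$logLik, 2 * f1$logLik, tolerance = 1e-6)
})

test_that("fit methods expose the usual modelling surface", {
  cells <- noiseless_hill_cells(0.3, 0.6, 9, n_per_cell = 1e5)
  fit <- evac_fit(cells, model = "hill")
  expect_named(coef(fit), c("r_max", "theta", "h"))
  expect_s3_class(logLik(fit), "logLik")
  expect_length(fitted(fit), nrow(fit$cells))
  expect_length(residuals(fit), nrow(fit$cells))
  expect_equal(predict(fit, data.frame(q = 0.6)),
               hill_rate(0.6, coef(fit)[["r_max"]], coef(fit)[["theta"]],
                         coef(fit)[["h"]]))
  m <- as_evac_model(fit)
  expect_s3_class(m, "evac_model")
  expect_equal(m$r_T1, coef(fit)[["r_max"]])
})
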