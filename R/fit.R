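#' Count-level log-likelihood of a rate model
#'
#' The fit objective: treating every at-home second in cell k as an
#' independent Bernoulli trial with the model rate r_k, the log-likelihood
#' of the observed counts is `sum(m * log(r) + (n - m) * log(1 - r))`. This
#' is the count-level objective whose conjugate posterior per cell is the
#' Beta(m + 1, n - m + 1) distribution behind [beta_rate()]; the fit is to
#' the raw `m` and `n` counts, never to the measured `R` values.
#'
#' @param model_rates per-cell model rates in (0, 1) (clamped at 1e-9 from
#'   the boundaries).
#' @param cells a `rate_cells` data frame with columns `m`, `n`; all cells
#'   must have `n > 0` (pre-filter unobserved cells).
#' @return The log-likelihood (scalar).
#' @export
count_log_likelihood <- function(model_rates, cells) {
  if (any(cells$n == 0)) stop("cells with n = 0 must be excluded from fitting")
  if (length(model_rates) != nrow(cells))
    stop("`model_rates` must match the number of cells")
  eps <- 1e-9
  r <- pmin(pmax(model_rates, eps), 1 - eps)
  sum(cells$m * log(r) + (cells$n - cells$m) * log1p(-r))
}

# Rates implied by a parameter vector for each fit family.
# Out-of-(0,1) thresholds are clamped; the caller adds a penalty.
.eval_rates <- function(par, cells, family) {
  h <- par[["h"]]
  theta <- switch(family,
    hill = rep_len(par[["theta"]], nrow(cells)),
    capacity = ,
    sixparam = par[["theta0"]] + par[["c"]] * cells$capacity)
  r_max <- switch(family,
    hill = ,
    capacity = rep_len(par[["r_max"]], nrow(cells)),
    sixparam = unname(c(T1 = par[["r_T1"]], T2 = par[["r_T2"]],
                        T3 = par[["r_T3"]])[cells$window]))
  th <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
  qh <- cells$q^h
  list(rates = r_max * qh / (qh + th^h),
       penalty = sum((theta - th)^2))
}

.fit_bounds <- function(family) {
  switch(family,
    hill = list(lower = c(r_max = 1e-4, theta = 0.02, h = 0.5),
                upper = c(r_max = 1, theta = 0.98, h = 40)),
    capacity = list(lower = c(r_max = 1e-4, h = 0.5, theta0 = 0.02, c = -0.018),
                    upper = c(r_max = 1, h = 40, theta0 = 0.98, c = 0.018)),
    sixparam = list(lower = c(h = 0.5, r_T1 = 1e-4, r_T2 = 1e-4, r_T3 = 1e-4,
                              theta0 = 0.02, c = -0.018),
                    upper = c(h = 40, r_T1 = 1, r_T2 = 1, r_T3 = 1,
                              theta0 = 0.98, c = 0.018)))
}

# Multi-start lattice: 27 starts over threshold x steepness x rate scale.
.fit_starts <- function(family) {
  grid <- expand.grid(theta = c(0.3, 0.55, 0.8), h = c(2, 6, 15),
                      r = c(0.05, 0.2, 0.5))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    switch(family,
      hill = c(r_max = g$r, theta = g$theta, h = g$h),
      capacity = c(r_max = g$r, h = g$h, theta0 = g$theta, c = 0),
      sixparam = c(h = g$h, r_T1 = g$r, r_T2 = g$r, r_T3 = g$r,
                   theta0 = g$theta, c = 0))
  })
}

#' Fit a Hill-function decision model to cell counts
#'
#' Fits the evacuation decision law by maximizing the count-level
#' log-likelihood ([count_log_likelihood()]) over a multi-start lattice of
#' at least 27 initial points refined by box-constrained local optimization.
#' Three nested families are available:
#'
#' * `"hill"` -- the three-parameter population law
#'   `r(q) = r_max q^h / (q^h + theta^h)`, for cells partitioned by
#'   likelihood only (or per individual).
#' * `"capacity"` -- shared `r_max` and `h`, with the threshold a linear
#'   function of shelter capacity, `theta(B) = theta0 + c B` (4 parameters);
#'   requires at least two observed capacity levels.
#' * `"sixparam"` -- additionally one maximum rate per time-urgency window
#'   (`r_T1`, `r_T2`, `r_T3`); requires all three windows observed.
#'
#' @param x a `rate_cells` data frame (see [aggregate_counts()]) or a list
#'   of `run_log`s, which is aggregated with the scheme the family needs.
#' @param model fit family: `"hill"`, `"capacity"`, or `"sixparam"`.
#' @param control list overriding optimizer settings: `rel.tol`
#'   (convergence tolerance, default 1e-8), `starts` (list of named start
#'   vectors replacing the default lattice).
#' @return An object of class `evac_fit`: coefficients, maximized
#'   log-likelihood, the cells used, convergence diagnostics, and a
#'   `degenerate` flag (set when no evacuations were observed or a rate
#'   parameter is pinned to its lower bound).
#' @seealso [bootstrap_params()] for parameter uncertainties, [loocv()],
#'   [expected_at_home()] for forward prediction.
#' @export
evac_fit <- function(x, model = c("hill", "capacity", "sixparam"),
                     control = list()) {
  family <- match.arg(model)
  if (!inherits(x, "rate_cells")) {
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), "run_log")))
      stop("`x` must be a `rate_cells` table or a list of run logs")
    scheme <- switch(family, hill = "by_q", capacity = "by_q_B",
                     sixparam = "by_q_B_T")
    x <- rate_table(x, scheme)
  }
  cells <- x[x$n > 0, , drop = FALSE]
  if (nrow(cells) < 3L) stop("need at least 3 observed cells")
  if (family %in% c("capacity", "sixparam")) {
    if (is.null(cells$capacity) || length(unique(cells$capacity)) < 2L)
      stop("capacity-dependent fits need >= 2 shelter-capacity levels; ",
           "use model = \"hill\" for pooled data")
  }
  if (family == "sixparam") {
    if (is.null(cells$window) ||
        !all(c("T1", "T2", "T3") %in% unique(cells$window)))
      stop("six-parameter fits need observations in all three time windows")
  }

  rel.tol <- if (is.null(control$rel.tol)) 1e-8 else control$rel.tol
  starts <- if (is.null(control$starts)) .fit_starts(family) else control$starts
  bounds <- .fit_bounds(family)
  negll <- function(par) {
    names(par) <- names(bounds$lower)
    ev <- .eval_rates(par, cells, family)
    -count_log_likelihood(ev$rates, cells) + 1e8 * ev$penalty
  }
  best <- NULL
  for (st in starts) {
    fit <- stats::nlminb(st[names(bounds$lower)], negll,
                         lower = bounds$lower, upper = bounds$upper,
                         control = list(rel.tol = rel.tol, iter.max = 500,
                                        eval.max = 1000))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  par <- best$par
  names(par) <- names(bounds$lower)
  rate_names <- grep("^r", names(par), value = TRUE)
  degenerate <- sum(cells$m) == 0 ||
    any(par[rate_names] <= bounds$lower[rate_names] * 1.01)
  ll <- count_log_likelihood(.eval_rates(par, cells, family)$rates, cells)
  structure(list(coefficients = par, logLik = ll,
                 family = family, cells = cells, n_cells = nrow(cells),
                 convergence = best$convergence, message = best$message,
                 degenerate = degenerate, boot_sd = NULL),
            class = "evac_fit")
}

#' @export
print.evac_fit <- function(x, ...) {
  cat(sprintf("Evacuation decision model (%s family), %d cells\n",
              x$family, x$n_cells))
  print(round(x$coefficients, 5))
  cat(sprintf("log-likelihood: %.2f\n", x$logLik))
  if (x$degenerate) cat("note: fit flagged degenerate\n")
  invisible(x)
}

#' @export
coef.evac_fit <- function(object, ...) object$coefficients

#' @export
logLik.evac_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = sum(object$cells$n), class = "logLik")
}

#' @export
summary.evac_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients)
  if (!is.null(object$boot_sd)) tab$boot_sd <- object$boot_sd[rownames(tab)]
  structure(list(family = object$family, table = tab, logLik = object$logLik,
                 n_cells = object$n_cells, degenerate = object$degenerate),
            class = "summary.evac_fit")
}

#' @export
print.summary.evac_fit <- function(x, ...) {
  cat(sprintf("Evacuation decision model, %s family\n", x$family))
  print(round(x$table, 5))
  cat(sprintf("log-likelihood %.2f on %d cells\n", x$logLik, x$n_cells))
  if (x$degenerate) cat("note: fit flagged degenerate\n")
  invisible(x)
}

#' @export
fitted.evac_fit <- function(object, ...) {
  .eval_rates(object$coefficients, object$cells, object$family)$rates
}

#' @export
residuals.evac_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  res <- object$cells$R - fitted(object)
  if (type == "pearson") res <- res / object$cells$sd
  res
}

#' Predict rates from a fitted decision model
#'
#' @param object an `evac_fit`.
#' @param newdata data frame with column `q` and, as the family requires,
#'   `capacity` and `window`; defaults to the fitted cells.
#' @param ... unused.
#' @return Per-second evacuation rates.
#' @export
predict.evac_fit <- function(object, newdata = object$cells, ...) {
  need <- switch(object$family, hill = "q", capacity = c("q", "capacity"),
                 sixparam = c("q", "capacity", "window"))
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stop("`newdata` lacks column(s): ", paste(miss, collapse = ", "))
  .eval_rates(object$coefficients, newdata, object$family)$rates
}

#' Convert a fit to a generative decision model
#'
#' Lifts any fitted family to the full six-parameter law: the hill family
#' uses its single rate in all windows and a capacity-independent threshold;
#' the capacity family shares its rate across windows.
#'
#' @param fit an `evac_fit`.
#' @return An [evac_model()].
#' @export
as_evac_model <- function(fit) {
  stopifnot(inherits(fit, "evac_fit"))
  p <- as.list(fit$coefficients)
  switch(fit$family,
    hill = evac_model(h = p$h, r_T1 = p$r_max, r_T2 = p$r_max, r_T3 = p$r_max,
                      theta0 = p$theta, c = 0),
    capacity = evac_model(h = p$h, r_T1 = p$r_max, r_T2 = p$r_max,
                          r_T3 = p$r_max, theta0 = p$theta0, c = p$c),
    sixparam = evac_model(h = p$h, r_T1 = p$r_T1, r_T2 = p$r_T2,
                          r_T3 = p$r_T3, theta0 = p$theta0, c = p$c))
}

#' @export
simulate.evac_fit <- function(object, nsim = 1, seed = NULL,
                              design = make_design(), ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- as_evac_model(object)
  reps <- lapply(seq_len(nsim), function(i)
    generate_experiment(design, model,
                        seed = sample.int(.Machine$integer.max %/% 1000, 1)))
  if (nsim == 1) reps[[1]] else reps
}

#' @export
plot.evac_fit <- function(x, ...) {
  cells <- x$cells
  graphics::plot(cells$q, cells$R, ylim = c(0, max(cells$R + cells$sd)),
                 xlab = "displayed strike likelihood q",
                 ylab = "evacuation rate (1/s)",
                 main = sprintf("Measured rates and fitted %s model", x$family),
                 pch = 16, ...)
  graphics::arrows(cells$q, pmax(cells$R - cells$sd, 0), cells$q,
                   cells$R + cells$sd, angle = 90, code = 3, length = 0.02,
                   col = "grey60")
  qq <- seq(0, 1, by = 0.005)
  if (x$family == "hill") {
    graphics::lines(qq, predict(x, data.frame(q = qq)), lwd = 2)
  } else {
    combos <- unique(cells[intersect(c("capacity", "window"), names(cells))])
    for (i in seq_len(nrow(combos))) {
      nd <- cbind(q = qq, combos[rep(i, length(qq)), , drop = FALSE])
      graphics::lines(qq, predict(x, nd), col = i, lwd = 1.5)
    }
  }
  invisible(x)
}
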