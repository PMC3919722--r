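#' Hill-function evacuation rate
#'
#' The per-second evacuation rate of an at-home agent as a function of the
#' displayed strike likelihood: `r(q) = r_max * q^h / (q^h + theta^h)`.
#' `theta` is the half-maximum threshold (`r(theta) = r_max / 2`), and the
#' Hill coefficient `h` sets the steepness -- large `h` approaches a strict
#' threshold policy.
#'
#' @param q strike likelihood(s) in \[0, 1\].
#' @param r_max maximum rate, evacuations/second, in (0, 1\].
#' @param theta half-maximum threshold in (0, 1).
#' @param h Hill coefficient > 0.
#' @return Rates in \[0, r_max), vectorised over `q`.
#' @export
hill_rate <- function(q, r_max, theta, h) {
  if (any(q < 0 | q > 1)) stop("`q` must lie in [0, 1]")
  if (r_max <= 0 || r_max > 1) stop("`r_max` must lie in (0, 1]")
  if (theta <= 0 || theta >= 1) stop("`theta` must lie in (0, 1)")
  if (h <= 0) stop("`h` must be > 0")
  qh <- q^h
  r_max * qh / (qh + theta^h)
}

#' Six-parameter evacuation decision model
#'
#' The population decision law: a Hill-function hazard rate whose maximum
#' rate depends on the time-urgency window and whose threshold shifts
#' linearly with shelter capacity,
#' `r(q; B, T) = r_T * q^h / (q^h + theta(B)^h)` with
#' `theta(B) = theta0 + c * B`. The three windows are T1 (VariableTime,
#' before 30 s), T2 (VariableTime, at/after 30 s), and T3 (CertainTime).
#' Defaults are the package's reference population estimates.
#'
#' @param h Hill coefficient.
#' @param r_T1,r_T2,r_T3 maximum rates (evacuations/second) per window.
#' @param theta0 threshold offset.
#' @param c threshold slope per shelter bed; `theta0 + c * B` must stay in
#'   (0, 1) for capacities 10--50.
#' @return An object of class `evac_model`.
#' @export
evac_model <- function(h = 9.3, r_T1 = 0.07, r_T2 = 0.37, r_T3 = 0.13,
                       theta0 = 0.60, c = 0.002) {
  rates <- c(r_T1 = r_T1, r_T2 = r_T2, r_T3 = r_T3)
  if (any(rates <= 0 | rates > 1)) stop("maximum rates must lie in (0, 1]")
  if (h <= 0) stop("`h` must be > 0")
  th <- theta0 + c * c(10, 50)
  if (any(th <= 0 | th >= 1))
    stop("theta(B) = theta0 + c*B must lie in (0, 1) for B in [10, 50]")
  structure(list(h = h, r_T1 = r_T1, r_T2 = r_T2, r_T3 = r_T3,
                 theta0 = theta0, c = c),
            class = "evac_model")
}

#' @export
print.evac_model <- function(x, ...) {
  cat("Six-parameter evacuation decision model\n")
  cat(sprintf("  Hill coefficient h      : %.3g\n", x$h))
  cat(sprintf("  max rates (T1, T2, T3)  : %.3g, %.3g, %.3g evac/s\n",
              x$r_T1, x$r_T2, x$r_T3))
  cat(sprintf("  threshold theta(B)      : %.3g + %.3g * B\n", x$theta0, x$c))
  invisible(x)
}

#' @export
coef.evac_model <- function(object, ...) {
  unlist(object[c("h", "r_T1", "r_T2", "r_T3", "theta0", "c")])
}

#' Time-urgency window of an interval
#'
#' @param t 1-based one-second interval index; interval `t` covers
#'   \[t-1, t) seconds.
#' @param regime `"CertainTime"` or `"VariableTime"`.
#' @return `"T1"`, `"T2"`, or `"T3"`, vectorised over `t`.
#' @export
time_window <- function(t, regime) {
  if (regime == "CertainTime") rep("T3", length(t))
  else ifelse(t - 1 < 30, "T1", "T2")
}

#' Evaluate the decision law
#'
#' @param model an [evac_model()].
#' @param q displayed strike likelihood(s).
#' @param capacity shelter capacity in beds.
#' @param window `"T1"`, `"T2"`, or `"T3"` (recycled against `q`).
#' @return Per-second evacuation rates.
#' @export
evac_rate <- function(model, q, capacity, window) {
  stopifnot(inherits(model, "evac_model"))
  n <- max(length(q), length(window))
  q <- rep_len(q, n)
  window <- rep_len(window, n)
  r_max <- c(T1 = model$r_T1, T2 = model$r_T2, T3 = model$r_T3)[window]
  theta <- model$theta0 + model$c * capacity
  qh <- q^model$h
  unname(r_max * qh / (qh + theta^model$h))
}
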