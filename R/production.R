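#' Saturating turnover function of the energy state
#'
#' Default stand-in for the cytochrome c turnover model: a Hill-type function
#' of the inverse energy state, pcc(ES) = 1 / (1 + (ES/K)^h). It is strictly
#' decreasing in ES — as ATP is drawn down (ES falls) turnover rises toward
#' its maximum — and saturates as ES approaches zero. Only the ratio
#' pcc(ES)/pcc(base ES) enters the production rate, so the absolute scale is
#' irrelevant and any strictly decreasing turnover preserves the rest
#' calibration. A user-supplied turnover function (e.g. an implementation of
#' a full oxidative-phosphorylation turnover model) can be used instead.
#'
#' @param k Half-maximal energy state (1/mM). Default 0.5, giving roughly a
#'   50-fold turnover headroom above the resting state (base ES ~ 23.7/mM).
#' @param h Hill exponent, positive. Default 1.
#' @return A function mapping ES (1/mM) to relative turnover.
#' @export
hill_turnover <- function(k = 0.5, h = 1) {
  stopifnot(k > 0, h > 0)
  f <- function(es) 1 / (1 + (es / k)^h)
  # parameters retained so the compiled simulation engine can evaluate the
  # same function natively
  structure(f, class = c("hill_turnover", "function"), k = k, h = h)
}

#' Energy-state-regulated ATP production model
#'
#' ATP production is the turnover rate times the (never explicitly needed)
#' cytochrome c concentration; the latter is fixed by requiring production at
#' the resting state to equal the terminal's rest consumption rate, which
#' reduces the rate to
#' `p(ES) = base_rate * turnover(ES) / turnover(base_es)`,
#' subsequently soft-capped at `max_rate` (see [cap_production()]).
#'
#' @param base_rate Rest consumption rate (mM/s), reused as rest production.
#' @param base_es Energy state at the resting state (1/mM).
#' @param max_rate Maximum production rate (mM/s), usually
#'   `max_rate_per_density * mito_density`.
#' @param turnover Strictly decreasing function of ES; default
#'   [hill_turnover()].
#' @param cap_exponent Soft-cap exponent (default 5).
#' @return An object of class `production_model`.
#' @export
production_model <- function(base_rate, base_es, max_rate,
                             turnover = hill_turnover(),
                             cap_exponent = 5) {
  stopifnot(base_rate >= 0, base_es > 0, max_rate > 0, cap_exponent > 0,
            is.function(turnover))
  structure(list(base_rate = base_rate, base_es = base_es,
                 max_rate = max_rate, turnover = turnover,
                 turnover_base = turnover(base_es),
                 cap_exponent = cap_exponent),
            class = "production_model")
}

#' Production model for a terminal at a given resting state
#'
#' Convenience constructor: takes `base_rate` and `mito_density *
#' max_rate_per_density` from the terminal and `base_es` from the resting
#' state.
#'
#' @param params A [terminal_params()].
#' @param rest_state A [metabolic_state()] (the calibration point).
#' @param turnover,cap_exponent See [production_model()].
#' @return A `production_model`.
#' @export
production_model_for <- function(params, rest_state,
                                 turnover = hill_turnover(),
                                 cap_exponent = 5) {
  production_model(base_rate = params$base_rate,
                   base_es = energy_state(rest_state),
                   max_rate = params$max_rate_per_density * params$mito_density,
                   turnover = turnover, cap_exponent = cap_exponent)
}

#' Soft production cap
#'
#' Smoothly caps a rate at `max_rate` via
#' `(p^-e + max_rate^-e)^(-1/e)` with exponent `e` (default 5): for
#' `p << max_rate` the result is essentially `p`, for `p >> max_rate` it
#' approaches `max_rate`, and it is always below both.
#'
#' @param p Uncapped rate(s) (mM/s), non-negative.
#' @param max_rate Cap (mM/s), positive.
#' @param exponent Cap exponent, positive.
#' @return Capped rate(s).
#' @export
cap_production <- function(p, max_rate, exponent = 5) {
  stopifnot(all(p >= 0), max_rate > 0, exponent > 0)
  out <- (p^(-exponent) + max_rate^(-exponent))^(-1 / exponent)
  out[p == 0] <- 0
  out
}

#' ATP production rate for a metabolic state
#'
#' @param state A [metabolic_state()].
#' @param m A [production_model()].
#' @param capped Apply the soft cap (default `TRUE`).
#' @return Production rate (mM/s).
#' @export
production_rate <- function(state, m, capped = TRUE) {
  stopifnot(inherits(m, "production_model"))
  es <- energy_state(state)
  p <- m$base_rate * m$turnover(es) / m$turnover_base
  if (capped) p <- cap_production(p, m$max_rate, m$cap_exponent)
  p
}

#' Time derivative of a production-rate series
#'
#' Centred finite differences on a uniformly sampled series; one-sided at the
#' endpoints.
#'
#' @param series Numeric vector (mM/s), uniformly sampled.
#' @param dt Sampling interval (s).
#' @return Numeric vector of accelerations (mM/s^2), same length.
#' @export
production_acceleration <- function(series, dt) {
  n <- length(series)
  if (n < 3) stop("production_acceleration needs at least 3 points",
                  call. = FALSE)
  stopifnot(dt > 0)
  acc <- numeric(n)
  acc[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) / (2 * dt)
  acc[1] <- (series[2] - series[1]) / dt
  acc[n] <- (series[n] - series[n - 1]) / dt
  acc
}
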