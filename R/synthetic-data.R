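# Default per-component draw ranges for synthetic terminal parameters.
# These magnitudes are anchored to the model's printed context (mM-scale
# concentrations, production caps of 0.079/0.154 mM/s/1%, type-Ib
# mitochondrial densities near 6.3%) but are NOT measured values for any
# terminal: they are synthetic stand-ins.
default_terminal_ranges <- function() {
  list(
    n_atp = list(Na = c(0.8e6, 1.6e6), Ca = c(0.5e6, 0.9e6),
                 NT1 = c(0.3e6, 0.7e6), NT2 = c(0.25e6, 0.55e6),
                 NT3 = c(0.2e6, 0.4e6)),
    tau = list(Na = c(0.05, 0.15), Ca = c(0.2, 0.4), NT1 = c(0.7, 1.4),
               NT2 = c(3, 6), NT3 = c(10, 20)),
    base_rate = c(0.015, 0.025),
    volume = c(350, 450),
    mito_density = c(5, 7))
}

#' Specification for the synthetic-data generators
#'
#' @param seed Integer seed; all generators are deterministic functions of the
#'   spec (same seed, same output).
#' @param terminal_ranges Per-field low/high bounds for
#'   [gen_terminal_params()]; see `default_terminal_ranges` in the package
#'   source for the defaults and their rationale.
#' @param tau_bleach Ratio-level bleach time constant (s) programmed into
#'   generated traces.
#' @param response_amplitude Programmed peak dR/R of the stimulus-locked
#'   response.
#' @param response_rise,response_decay Response kinetics (s).
#' @param noise_sd Additive intensity noise (per channel, per sample).
#' @param sampling_rate Ratio sampling rate (Hz); default 4 (four image pairs
#'   per second).
#' @param mejp_mean,mejp_cv Miniature-EJP amplitude mean (mV) and coefficient
#'   of variation.
#' @param quantal_count True quantal content programmed into EJP samples.
#' @param n_ejp,n_mejp Sample sizes (defaults 10 evoked, 30 miniature).
#' @param driving Effective driving force (mV) used to distort EJPs by the
#'   inverse of the non-linear summation correction.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           terminal_ranges = default_terminal_ranges(),
                           tau_bleach = 100, response_amplitude = 0.3,
                           response_rise = 1, response_decay = 8,
                           noise_sd = 0.5, sampling_rate = 4,
                           mejp_mean = 1, mejp_cv = 0.3,
                           quantal_count = 40, n_ejp = 10, n_mejp = 30,
                           driving = 120) {
  stopifnot(noise_sd >= 0, sampling_rate > 0, tau_bleach > 0,
            mejp_mean > 0, mejp_cv >= 0, quantal_count > 0,
            n_ejp >= 1, n_mejp >= 1, driving > 0)
  structure(list(seed = as.integer(seed), terminal_ranges = terminal_ranges,
                 tau_bleach = tau_bleach,
                 response_amplitude = response_amplitude,
                 response_rise = response_rise,
                 response_decay = response_decay,
                 noise_sd = noise_sd, sampling_rate = sampling_rate,
                 mejp_mean = mejp_mean, mejp_cv = mejp_cv,
                 quantal_count = quantal_count, n_ejp = n_ejp,
                 n_mejp = n_mejp, driving = driving),
            class = "generator_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Draw a synthetic terminal parameter set
#'
#' Uniform draws within the spec's per-field bounds. The result is flagged
#' `synthetic = TRUE`: these are stand-ins with plausible magnitudes, not
#' measured per-terminal values; a measured set can be loaded with
#' [read_terminal_config()].
#'
#' @param spec A [generator_spec()].
#' @param name Terminal label.
#' @return A [terminal_params()].
#' @export
gen_terminal_params <- function(spec = generator_spec(),
                                name = "synthetic-Ib") {
  r <- spec$terminal_ranges
  with_seed(spec$seed, {
    n_atp <- vapply(COMPONENTS,
                    function(j) runif(1, r$n_atp[[j]][1], r$n_atp[[j]][2]),
                    numeric(1))
    tau <- vapply(COMPONENTS,
                  function(j) runif(1, r$tau[[j]][1], r$tau[[j]][2]),
                  numeric(1))
    terminal_params(name = name, n_atp = n_atp, tau = tau,
                    base_rate = runif(1, r$base_rate[1], r$base_rate[2]),
                    volume = runif(1, r$volume[1], r$volume[2]),
                    mito_density = runif(1, r$mito_density[1],
                                         r$mito_density[2]),
                    synthetic = TRUE)
  })
}

#' Fixed synthetic terminal (midpoint parameters)
#'
#' The midpoints of the generator bounds: a deterministic, clearly synthetic
#' type-Ib-like terminal used as the default simulation input. Average
#' consumption under the 42 Hz locomotion protocol is ~0.45 mM/s, inside the
#' envelope set by the measured production caps.
#'
#' @param ... Overrides passed to [terminal_params()].
#' @return A [terminal_params()].
#' @export
default_terminal <- function(...) {
  r <- default_terminal_ranges()
  mid <- function(b) (b[1] + b[2]) / 2
  args <- list(name = "synthetic-Ib",
               n_atp = vapply(r$n_atp, mid, numeric(1)),
               tau = vapply(r$tau, mid, numeric(1)),
               base_rate = mid(r$base_rate),
               volume = mid(r$volume),
               mito_density = mid(r$mito_density),
               synthetic = TRUE)
  override <- list(...)
  args[names(override)] <- override
  do.call(terminal_params, args)
}

#' Generate a synthetic ratiometric trace with known ground truth
#'
#' Both channels bleach with a common monoexponential (which cancels in the
#' ratio); an additional bleach with time constant `tau_bleach` is applied to
#' the numerator only, so the ratio itself decays with `tau_bleach` (what the
#' bleach correction must remove). A stimulus-locked response of programmed
#' peak dR/R (difference-of-exponentials kinetics) multiplies the numerator,
#' and independent Gaussian noise is added to every channel. Two constant
#' background regions per channel are included.
#'
#' @param spec A [generator_spec()].
#' @param t_range Time range (s); stimulus onset is at 0 s.
#' @param stim_duration Stimulus duration (s).
#' @return A [ratiometric_trace()] with attribute `ground_truth` (list with
#'   `tau_bleach`, `peak_dr_r`, `noise_sd`).
#' @export
gen_ratiometric_trace <- function(spec = generator_spec(),
                                  t_range = c(-30, 40), stim_duration = 10) {
  time <- seq(t_range[1], t_range[2], by = 1 / spec$sampling_rate)
  f0_num <- 1000; f0_den <- 800; bg_level <- 100
  common_tau <- 300

  resp <- rep(0, length(time))
  on <- time >= 0
  tr <- time[on]
  shape <- (1 - exp(-tr / spec$response_rise)) * exp(-tr / spec$response_decay)
  if (max(shape) > 0) shape <- shape / max(shape)
  resp[on] <- spec$response_amplitude * shape

  common <- exp(-(time - t_range[1]) / common_tau)
  ratio_bleach <- exp(-(time - t_range[1]) / spec$tau_bleach)

  with_seed(spec$seed + 1L, {
    noise <- matrix(rnorm(6 * length(time), sd = spec$noise_sd),
                    ncol = 6)
    trace <- ratiometric_trace(
      time = time,
      signal_num = f0_num * common * ratio_bleach * (1 + resp) + bg_level +
        noise[, 1],
      signal_den = f0_den * common + bg_level + noise[, 2],
      background_num = cbind(bg_level + noise[, 3], bg_level + noise[, 4]),
      background_den = cbind(bg_level + noise[, 5], bg_level + noise[, 6]),
      stim_start = 0, stim_end = stim_duration)
  })
  attr(trace, "ground_truth") <- list(tau_bleach = spec$tau_bleach,
                                      peak_dr_r = spec$response_amplitude,
                                      noise_sd = spec$noise_sd)
  trace
}

#' Generate synthetic EJP/mEJP amplitude samples with known quantal content
#'
#' Miniature amplitudes are drawn from a zero-truncated normal with the spec's
#' mean and CV. Evoked amplitudes are built so that [quantal_content()]
#' recovers the programmed count: the true corrected mean EJP is
#' `quantal_count * mejp_mean`, and samples are distorted by the inverse of
#' the non-linear summation correction before noise is applied.
#'
#' @param spec A [generator_spec()].
#' @return List with `ejp`, `mejp`, `driving`, and attribute `ground_truth`
#'   (the programmed quantal count).
#' @export
gen_amplitude_samples <- function(spec = generator_spec()) {
  corrected_true <- spec$quantal_count * spec$mejp_mean
  if (corrected_true <= 0 || spec$driving <= 0) {
    stop("invalid amplitude spec", call. = FALSE)
  }
  # invert v_corr = v/(1 - v/D): v = v_corr * D / (D + v_corr)
  ejp_true <- corrected_true * spec$driving / (spec$driving + corrected_true)
  out <- with_seed(spec$seed + 2L, {
    mejp <- rnorm(spec$n_mejp, mean = spec$mejp_mean,
                  sd = spec$mejp_cv * spec$mejp_mean)
    while (any(mejp <= 0)) {
      mejp[mejp <= 0] <- rnorm(sum(mejp <= 0), mean = spec$mejp_mean,
                               sd = spec$mejp_cv * spec$mejp_mean)
    }
    # evoked amplitudes scatter with CV reduced by the quantal count
    ejp_cv <- spec$mejp_cv / sqrt(spec$quantal_count)
    ejp <- rnorm(spec$n_ejp, mean = ejp_true, sd = ejp_cv * ejp_true)
    while (any(ejp <= 0)) {
      ejp[ejp <= 0] <- rnorm(sum(ejp <= 0), mean = ejp_true,
                             sd = ejp_cv * ejp_true)
    }
    list(ejp = ejp, mejp = mejp, driving = spec$driving)
  })
  attr(out, "ground_truth") <- list(quantal_count = spec$quantal_count)
  out
}
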