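COMPONENTS <- c("Na", "Ca", "NT1", "NT2", "NT3")

#' Per-terminal energetic parameters
#'
#' Describes one motor-neuron terminal: the per-action-potential ATP cost and
#' decay time constant of each signalling component (Na+ extrusion, Ca2+
#' extrusion and three synaptic-vesicle recycling/refilling components tied to
#' neurotransmitter release), a constant non-signalling base consumption rate,
#' the terminal volume used to convert molecule counts to concentrations, and
#' the mitochondrial volume density that scales the production cap.
#'
#' @param name Label for the terminal.
#' @param n_atp Named numeric vector of ATP molecules consumed per AP, names
#'   `Na`, `Ca`, `NT1`, `NT2`, `NT3`; all non-negative.
#' @param tau Named numeric vector of decay constants (s), same names, all
#'   positive.
#' @param base_rate Non-signalling consumption rate (mM/s), non-negative.
#' @param volume Terminal volume (um^3), positive.
#' @param mito_density Mitochondrial volume density (percent, in (0, 100]).
#' @param max_rate_per_density Production cap per 1% mitochondrial density
#'   (mM/s/1%); the measured presets are 0.079 (larval brain) and 0.154
#'   (adult thorax).
#' @param phosphagen_present Whether the arginine-kinase reaction is enforced.
#' @param synthetic Flag recorded in metadata: `TRUE` marks parameter sets
#'   drawn by the synthetic generator rather than measured.
#' @return An object of class `terminal_params`.
#' @export
terminal_params <- function(name = "terminal",
                            n_atp,
                            tau,
                            base_rate,
                            volume,
                            mito_density,
                            max_rate_per_density = 0.154,
                            phosphagen_present = TRUE,
                            synthetic = FALSE) {
  n_atp <- n_atp[COMPONENTS]; tau <- tau[COMPONENTS]
  if (any(is.na(n_atp)) || any(is.na(tau))) {
    stop("n_atp and tau must be named vectors with components ",
         paste(COMPONENTS, collapse = ", "), call. = FALSE)
  }
  if (any(n_atp < 0)) stop("all n_atp must be >= 0", call. = FALSE)
  if (any(tau <= 0)) stop("all tau must be > 0", call. = FALSE)
  if (base_rate < 0) stop("base_rate must be >= 0", call. = FALSE)
  if (volume <= 0) stop("volume must be > 0", call. = FALSE)
  if (mito_density <= 0 || mito_density > 100) {
    stop("mito_density must be in (0, 100]", call. = FALSE)
  }
  if (max_rate_per_density <= 0) {
    stop("max_rate_per_density must be > 0", call. = FALSE)
  }
  structure(list(name = name, n_atp = n_atp, tau = tau,
                 base_rate = base_rate, volume = volume,
                 mito_density = mito_density,
                 max_rate_per_density = max_rate_per_density,
                 phosphagen_present = isTRUE(phosphagen_present),
                 synthetic = isTRUE(synthetic)),
            class = "terminal_params")
}

# Per-AP cost of each component expressed in mM (molecules / volume).
component_cost_mM <- function(params) {
  molecules_to_mM(params$n_atp, params$volume)
}

#' Firing protocol
#'
#' A repeating stimulation pattern. A full cycle is the span from the start of
#' one spike train to the start of the next; the duty cycle is the firing
#' portion of it. Within the duty window spikes occur every `1/rate` seconds,
#' at both the start and (when `duty * rate` is integral) the end of the
#' window, so a 10 Hz train with a 0.6 s duty fires 7 spikes.
#'
#' @param rate Firing rate (Hz), positive.
#' @param duty Duty cycle (s), in \[0, full_cycle\].
#' @param full_cycle Full cycle length (s), positive.
#' @param n_cycles Number of cycles, >= 1.
#' @param t_start Start time of the first cycle (s).
#' @param inclusive_end If `FALSE`, drop the spike that falls exactly at the
#'   end of the duty window (alternative endpoint convention).
#' @return An object of class `firing_protocol`.
#' @export
firing_protocol <- function(rate, duty, full_cycle, n_cycles = 1,
                            t_start = 0, inclusive_end = TRUE) {
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (duty < 0 || duty > full_cycle) {
    stop("duty must lie in [0, full_cycle]", call. = FALSE)
  }
  if (full_cycle <= 0) stop("full_cycle must be > 0", call. = FALSE)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  structure(list(rate = rate, duty = duty, full_cycle = full_cycle,
                 n_cycles = as.integer(n_cycles), t_start = t_start,
                 inclusive_end = isTRUE(inclusive_end)),
            class = "firing_protocol")
}

#' Preset firing protocols
#'
#' The four stimulation protocols used throughout: `"locomotion"` (42 Hz,
#' 0.8 s duty, 1 s full cycle, 240 cycles: 8160 APs over 4 min),
#' `"ca_pumping"` (50 Hz, 2 s duty, 4 s full cycle, 60 cycles: 6060 APs),
#' `"train60"` (a single 60 Hz train of 30 APs) and `"train80"` (a single
#' 80 Hz, 10 s train).
#'
#' @param name One of `"locomotion"`, `"ca_pumping"`, `"train60"`, `"train80"`.
#' @return A [firing_protocol()].
#' @export
protocol_preset <- function(name = c("locomotion", "ca_pumping",
                                     "train60", "train80")) {
  name <- match.arg(name)
  switch(name,
    locomotion = firing_protocol(rate = 42, duty = 0.8, full_cycle = 1,
                                 n_cycles = 240),
    ca_pumping = firing_protocol(rate = 50, duty = 2, full_cycle = 4,
                                 n_cycles = 60),
    train60 = firing_protocol(rate = 60, duty = 29 / 60, full_cycle = 1,
                              n_cycles = 1),
    train80 = firing_protocol(rate = 80, duty = 10, full_cycle = 12,
                              n_cycles = 1))
}

# Number of spikes in each cycle under the endpoint convention; a small
# tolerance keeps duty * rate from losing its terminal spike to round-off.
spikes_per_cycle <- function(p) {
  k_max <- floor(p$duty * p$rate + 1e-9)
  if (!p$inclusive_end && abs(k_max - p$duty * p$rate) < 1e-9 && k_max > 0) {
    k_max <- k_max - 1
  }
  as.integer(k_max) + 1L
}

#' Spike times of a firing protocol
#'
#' @param p A [firing_protocol()].
#' @return Object of class `spike_train`: a strictly increasing numeric vector
#'   of spike times (s).
#' @export
spike_times <- function(p) {
  stopifnot(inherits(p, "firing_protocol"))
  n_in <- spikes_per_cycle(p)
  k <- seq_len(n_in) - 1
  times <- as.vector(outer(k / p$rate,
                           p$t_start + (seq_len(p$n_cycles) - 1) * p$full_cycle,
                           "+"))
  structure(sort(times), class = "spike_train")
}

#' Total number of action potentials in one or more protocols
#'
#' @param protocols A [firing_protocol()] or a list of them.
#' @return Integer total spike count.
#' @export
count_action_potentials <- function(protocols) {
  if (inherits(protocols, "firing_protocol")) protocols <- list(protocols)
  sum(vapply(protocols,
             function(p) p$n_cycles * spikes_per_cycle(p),
             integer(1)))
}

#' ATP consumption rate at given times
#'
#' Evaluates the consumption model: a constant non-signalling base rate plus,
#' for every past spike and every signalling component j, a transient of
#' initial height N_j / tau_j decaying exponentially with time constant tau_j.
#' Transients from successive spikes summate. Molecule counts are converted to
#' mM via the terminal volume, so the result is in mM/s.
#'
#' @param t Numeric vector of evaluation times (s).
#' @param train A [spike_times()] result (or numeric vector of spike times).
#' @param params A [terminal_params()].
#' @return Numeric vector of consumption rates (mM/s), one per element of `t`.
#' @export
consumption_rate <- function(t, train, params) {
  stopifnot(inherits(params, "terminal_params"))
  ts <- as.numeric(train)
  cost <- component_cost_mM(params)   # mM per AP per component
  vapply(t, function(ti) {
    past <- ts[ts <= ti]
    if (length(past) == 0) return(params$base_rate)
    acc <- 0
    for (j in seq_along(COMPONENTS)) {
      acc <- acc + sum(cost[j] / params$tau[j] *
                         exp((past - ti) / params$tau[j]))
    }
    params$base_rate + acc
  }, numeric(1))
}

#' Consumption rate on a uniform grid via running decay accumulators
#'
#' Equivalent to [consumption_rate()] on a uniform grid but computed with one
#' exponential-decay accumulator per component, the scheme the simulator uses
#' internally (each spike deposits its height at the nearest grid point).
#'
#' @param times Uniform time grid (s).
#' @param train Spike times.
#' @param params A [terminal_params()].
#' @return Numeric vector of consumption rates (mM/s).
#' @export
consumption_series <- function(times, train, params) {
  stopifnot(length(times) >= 2)
  dt <- times[2] - times[1]
  ts <- as.numeric(train)
  cost <- component_cost_mM(params)
  idx <- pmin(pmax(round((ts - times[1]) / dt) + 1, 1), length(times))
  deposit <- matrix(0, nrow = length(times), ncol = length(COMPONENTS))
  for (j in seq_along(COMPONENTS)) {
    tab <- table(idx)
    deposit[as.integer(names(tab)), j] <- as.numeric(tab) * cost[j] /
      params$tau[j]
  }
  decay <- exp(-dt / params$tau)
  out <- numeric(length(times))
  acc <- numeric(length(COMPONENTS))
  for (i in seq_along(times)) {
    acc <- acc + deposit[i, ]
    out[i] <- params$base_rate + sum(acc)
    acc <- acc * decay
  }
  out
}

#' Total ATP consumed over a time window
#'
#' Integrates the consumption rate from 0 to `t_end`. For `t_end` well past
#' the last spike this converges to `base_rate * t_end` plus the full per-AP
#' budget `n_spikes * sum(N_j)` (volume-converted), since each transient
#' integrates to exactly N_j.
#'
#' @param train Spike times.
#' @param params A [terminal_params()].
#' @param t_end End of integration window (s).
#' @return ATP consumed (mM).
#' @export
integrated_cost <- function(train, params, t_end) {
  ts <- as.numeric(train)
  ts <- ts[ts <= t_end]
  cost <- component_cost_mM(params)
  total <- params$base_rate * t_end
  for (j in seq_along(COMPONENTS)) {
    # closed-form integral of each decaying transient up to t_end
    total <- total + sum(cost[j] * (1 - exp((ts - t_end) / params$tau[j])))
  }
  total
}
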