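#' Advance a metabolic state by one time step
#'
#' Implements the per-step update of the splitting scheme: consumption
#' converts ATP to ADP + Pi and production the reverse, so
#' `atp <- atp + dt * (production - consumption)` with the opposite change in
#' adp and pi; the two kinase equilibria are then re-enforced.
#'
#' @param state A [metabolic_state()].
#' @param dt Step (s), non-negative.
#' @param consumption Consumption rate at the step (mM/s).
#' @param production Capped production rate at the step (mM/s).
#' @param k [equilibrium_constants()].
#' @param opt [equilibration_options()]; `NULL` skips equilibration.
#' @return Updated [metabolic_state()].
#' @export
step_state <- function(state, dt, consumption, production,
                       k = equilibrium_constants(),
                       opt = equilibration_options()) {
  stopifnot(dt >= 0)
  flux <- (production - consumption) * dt
  atp <- state[["atp"]] + flux
  adp <- state[["adp"]] - flux
  pi_ <- state[["pi"]] - flux
  if (atp < 0 || adp < 0 || pi_ < 0) {
    stop("step would drive a concentration negative; refine dt", call. = FALSE)
  }
  s <- metabolic_state(atp, adp, state[["amp"]], state[["arg"]],
                       state[["argp"]], pi_)
  if (is.null(opt)) s else equilibrate(s, k, opt)
}

# Plain-R simulation engine, written independently of the compiled loop and
# kept as its reference: same splitting, same accumulator scheme.
simulate_engine_r <- function(state0, dt, n_steps, stride, spike_step,
                              comp_height, comp_tau, base_rate,
                              prod_model, k, equil_opt) {
  decay <- exp(-dt / comp_tau)
  acc <- numeric(length(comp_height))
  n_rec <- n_steps %/% stride + 1
  out <- matrix(NA_real_, nrow = n_rec, ncol = 9,
                dimnames = list(NULL, c("time", "atp", "adp", "amp", "arg",
                                        "argp", "pi", "consumption",
                                        "production")))
  s <- unclass(state0)
  sp <- 1; rec <- 1
  prod_at <- function(st) {
    if (is.null(prod_model)) return(0)
    es <- st[["atp"]] / (st[["adp"]] * st[["pi"]])
    p <- prod_model$base_rate * prod_model$turnover(es) /
      prod_model$turnover_base
    if (p > 0) {
      p <- (p^(-prod_model$cap_exponent) +
              prod_model$max_rate^(-prod_model$cap_exponent))^
        (-1 / prod_model$cap_exponent)
    }
    p
  }
  for (i in 0:n_steps) {
    while (sp <= length(spike_step) && spike_step[sp] == i + 1) {
      acc <- acc + comp_height
      sp <- sp + 1
    }
    cons <- base_rate + sum(acc)
    prod <- prod_at(s)
    if (i %% stride == 0) {
      out[rec, ] <- c(i * dt, s[["atp"]], s[["adp"]], s[["amp"]], s[["arg"]],
                      s[["argp"]], s[["pi"]], cons, prod)
      rec <- rec + 1
    }
    if (i == n_steps) break
    ok <- FALSE
    for (m in 0:10) {
      n_sub <- 2^m
      h <- dt / n_sub
      trial <- s
      ok <- TRUE
      for (u in seq_len(n_sub)) {
        flux <- (prod_at(trial) - cons) * h
        trial[["atp"]] <- trial[["atp"]] + flux
        trial[["adp"]] <- trial[["adp"]] - flux
        trial[["pi"]] <- trial[["pi"]] - flux
        if (trial[["atp"]] < 0 || trial[["adp"]] < 0 || trial[["pi"]] < 0) {
          ok <- FALSE
          break
        }
        if (!is.null(equil_opt)) {
          st <- metabolic_state(trial[["atp"]], trial[["adp"]], trial[["amp"]],
                                trial[["arg"]], trial[["argp"]], trial[["pi"]])
          trial <- unclass(equilibrate(st, k, equil_opt))
        }
      }
      if (ok) {
        s <- trial
        break
      }
    }
    if (!ok) {
      stop("simulation stopped at t = ", format(i * dt),
           " s: step would drive a concentration negative", call. = FALSE)
    }
    acc <- acc * decay
  }
  out
}

#' Simulate presynaptic ATP dynamics under a firing protocol
#'
#' Runs the operator-splitting integration: at each step ATP, ADP and Pi are
#' updated from the production and consumption rates (production recomputed
#' from the current energy state, consumption from per-component
#' exponential-decay accumulators fed by the spike train), then the
#' adenylate-kinase and (with phosphagen) arginine-kinase equilibria are
#' re-enforced. The production model is calibrated so that the resting state
#' is a steady state.
#'
#' @param params A [terminal_params()].
#' @param protocol A [firing_protocol()].
#' @param dt Integration step (s); a warning is given if it exceeds a tenth of
#'   the shortest decay constant.
#' @param t_end Simulation end (s); defaults to the protocol span.
#' @param record_dt Recording interval (s); must be an integer multiple of
#'   `dt`.
#' @param ic,k,thermo Initial conditions, equilibrium constants and
#'   thermodynamic constants.
#' @param turnover Turnover function for the production model (default
#'   [hill_turnover()]).
#' @param cap_exponent Soft-cap exponent.
#' @param phosphagen Enforce the arginine-kinase reaction; defaults to
#'   `params$phosphagen_present`.
#' @param production `FALSE` switches ATP production off entirely
#'   (diagnostic).
#' @param equil [equilibration_options()], or `NULL` to skip equilibration
#'   (diagnostic).
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (reference
#'   implementation). The compiled engine supports [hill_turnover()]-family
#'   turnover functions; other turnover functions require `engine = "r"`.
#' @return A `simulation_result`: a data frame with columns `time`, the six
#'   concentrations, `consumption`, `production`, `es`, `atp_adp`,
#'   `production_acceleration` and `free_energy`, with the run configuration
#'   in attributes.
#' @export
simulate_terminal <- function(params, protocol,
                              dt = 1e-4, t_end = NULL, record_dt = 0.01,
                              ic = initial_conditions(),
                              k = equilibrium_constants(),
                              thermo = thermo_constants(),
                              turnover = hill_turnover(),
                              cap_exponent = 5,
                              phosphagen = NULL,
                              production = TRUE,
                              equil = equilibration_options(),
                              engine = c("cpp", "r")) {
  stopifnot(inherits(params, "terminal_params"),
            inherits(protocol, "firing_protocol"))
  engine <- match.arg(engine)
  if (dt > min(params$tau) / 10) {
    warning("dt exceeds min(tau)/10; consumption transients may be ",
            "under-resolved", call. = FALSE)
  }
  if (is.null(t_end)) {
    t_end <- protocol$t_start + protocol$n_cycles * protocol$full_cycle
  }
  stride <- round(record_dt / dt)
  if (abs(stride * dt - record_dt) > 1e-9 * record_dt || stride < 1) {
    stop("record_dt must be a positive integer multiple of dt", call. = FALSE)
  }
  n_steps <- round(t_end / dt)

  if (is.null(phosphagen)) phosphagen <- params$phosphagen_present
  if (!is.null(equil)) {
    equil <- equilibration_options(tol = equil$tol, max_iter = equil$max_iter,
                                   enforce_phosphagen = phosphagen)
  }

  rest <- initial_state_from_equilibrium(ic, k)
  prod_model <- if (isTRUE(production)) {
    production_model_for(params, rest, turnover = turnover,
                         cap_exponent = cap_exponent)
  } else NULL

  train <- spike_times(protocol)
  ts <- as.numeric(train)
  ts <- ts[ts <= t_end + dt / 2]
  spike_step <- pmin(pmax(round(ts / dt) + 1L, 1L), n_steps + 1L)
  comp_height <- component_cost_mM(params) / params$tau

  if (engine == "cpp" && !is.null(prod_model) &&
      !inherits(prod_model$turnover, "hill_turnover")) {
    message("custom turnover function: using the R engine")
    engine <- "r"
  }

  if (engine == "cpp") {
    hk <- if (is.null(prod_model)) 1 else attr(prod_model$turnover, "k")
    hh <- if (is.null(prod_model)) 1 else attr(prod_model$turnover, "h")
    res <- .simulate_loop_cpp(
      unclass(rest), dt, as.integer(n_steps), as.integer(stride),
      as.integer(spike_step), comp_height, params$tau, params$base_rate,
      !is.null(prod_model),
      if (is.null(prod_model)) 0 else prod_model$base_rate,
      if (is.null(prod_model)) 1 else prod_model$turnover_base,
      hk, hh,
      if (is.null(prod_model)) 1 else prod_model$max_rate,
      cap_exponent,
      !is.null(equil), phosphagen,
      k$k_ad, k$k_ph,
      if (is.null(equil)) 1e-10 else equil$tol,
      if (is.null(equil)) 100L else equil$max_iter)
    if (nzchar(res$error)) {
      stop("simulation stopped at t = ", format(res$error_time), " s: ",
           res$error, call. = FALSE)
    }
    keep <- seq_len(res$n_recorded)
    mat <- cbind(time = res$time[keep], atp = res$atp[keep],
                 adp = res$adp[keep], amp = res$amp[keep],
                 arg = res$arg[keep], argp = res$argp[keep],
                 pi = res$pi[keep], consumption = res$consumption[keep],
                 production = res$production[keep])
  } else {
    mat <- simulate_engine_r(rest, dt, n_steps, stride, spike_step,
                             comp_height, params$tau, params$base_rate,
                             prod_model, k, equil)
  }

  df <- as.data.frame(mat)
  rt <- thermo$gas_constant * thermo$temperature
  df$es <- df$atp / (df$adp * df$pi)
  df$atp_adp <- df$atp / df$adp
  df$free_energy <- thermo$delta_g0 + rt * log(df$adp * df$pi / df$atp)
  df$production_acceleration <- if (nrow(df) >= 3) {
    production_acceleration(df$production, record_dt)
  } else NA_real_

  structure(df,
            class = c("simulation_result", "data.frame"),
            params = params, protocol = protocol, dt = dt,
            record_dt = record_dt, phosphagen = phosphagen,
            engine = engine, thermo = thermo, k = k, ic = ic)
}

#' @export
print.simulation_result <- function(x, ...) {
  p <- attr(x, "params"); pr <- attr(x, "protocol")
  cat("<simulation_result> terminal:", p$name,
      if (p$synthetic) "(synthetic parameters)" else "", "\n")
  cat(sprintf("  protocol: %g Hz, duty %g s / full cycle %g s x %d cycles\n",
              pr$rate, pr$duty, pr$full_cycle, pr$n_cycles))
  cat(sprintf("  phosphagen: %s | dt = %g s | %d samples over %g s\n",
              if (attr(x, "phosphagen")) "present" else "absent",
              attr(x, "dt"), nrow(x), x$time[nrow(x)]))
  cat(sprintf("  [ATP] range: %.4f - %.4f mM | |dG| range: %.2f - %.2f kJ/mol\n",
              min(x$atp), max(x$atp), min(abs(x$free_energy)),
              max(abs(x$free_energy))))
  invisible(x)
}

#' Within-cycle volatility of a simulated series
#'
#' Two summaries of how much a variable swings within firing cycles: the mean
#' per-cycle peak-to-trough amplitude, and the standard deviation of the
#' linearly detrended series.
#'
#' @param values Numeric series.
#' @param time Sample times (s), same length.
#' @param cycle_length Full-cycle length (s); `NULL` treats the whole series
#'   as one cycle.
#' @param t_start Start of the first cycle (s).
#' @return List with `per_cycle` (peak-to-trough per cycle),
#'   `mean_peak_to_trough` and `sd_detrended`.
#' @export
volatility <- function(values, time, cycle_length = NULL, t_start = time[1]) {
  stopifnot(length(values) == length(time))
  if (is.null(cycle_length)) {
    per_cycle <- max(values) - min(values)
  } else {
    idx <- floor((time - t_start) / cycle_length)
    idx[time < t_start] <- NA
    # a sample sitting exactly on the final cycle boundary belongs to the
    # last cycle rather than opening a degenerate one-point cycle
    last <- ceiling((max(time) - t_start) / cycle_length - 1e-9) - 1
    idx <- pmin(idx, max(last, 0))
    per_cycle <- tapply(values, idx, function(v) max(v) - min(v))
    per_cycle <- as.numeric(per_cycle)
  }
  detrended <- stats::residuals(stats::lm(values ~ time))
  list(per_cycle = per_cycle,
       mean_peak_to_trough = mean(per_cycle),
       sd_detrended = stats::sd(detrended))
}

#' Volatility of a variable in a simulation result
#'
#' @param result A `simulation_result`.
#' @param var Column name (default `"atp"`).
#' @return See [volatility()]; cycles taken from the run's protocol.
#' @export
simulation_volatility <- function(result, var = "atp") {
  pr <- attr(result, "protocol")
  volatility(result[[var]], result$time, cycle_length = pr$full_cycle,
             t_start = pr$t_start)
}

#' Paired simulation with and without the phosphagen system
#'
#' Runs the identical configuration twice, once with the arginine-kinase
#' reaction enforced and once without, and summarizes the contrast.
#'
#' @param params,protocol,... Passed to [simulate_terminal()].
#' @return List with elements `with`, `without` (simulation results) and
#'   `summary` (a data frame of ATP volatility and minima under each
#'   condition).
#' @export
compare_phosphagen <- function(params, protocol, ...) {
  with_ph <- simulate_terminal(params, protocol, phosphagen = TRUE, ...)
  without_ph <- simulate_terminal(params, protocol, phosphagen = FALSE, ...)
  smry <- data.frame(
    phosphagen = c(TRUE, FALSE),
    atp_volatility = c(simulation_volatility(with_ph)$mean_peak_to_trough,
                       simulation_volatility(without_ph)$mean_peak_to_trough),
    min_atp = c(min(with_ph$atp), min(without_ph$atp)),
    min_atp_adp = c(min(with_ph$atp_adp), min(without_ph$atp_adp)),
    min_abs_free_energy = c(min(abs(with_ph$free_energy)),
                            min(abs(without_ph$free_energy))))
  list(with = with_ph, without = without_ph, summary = smry)
}

#' Write a simulation result to a tidy CSV
#'
#' One row per recorded time with stable column names
#' (`time_s`, `atp_mM`, ..., `dG_kJ_mol`). `free_energy` is signed; the
#' available free energy is its magnitude.
#'
#' @param result A `simulation_result`.
#' @param path Output CSV path.
#' @param metadata_path Optional path for a YAML run-metadata document (all
#'   parameters of the run).
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(result, path, metadata_path = NULL) {
  out <- data.frame(time_s = result$time, atp_mM = result$atp,
                    adp_mM = result$adp, amp_mM = result$amp,
                    arg_mM = result$arg, argp_mM = result$argp,
                    pi_mM = result$pi,
                    consumption_mM_s = result$consumption,
                    production_mM_s = result$production,
                    es_per_mM = result$es, atp_adp = result$atp_adp,
                    dG_kJ_mol = result$free_energy)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(metadata_path)) {
    p <- attr(result, "params"); pr <- attr(result, "protocol")
    meta <- list(
      tool = paste0("presynATP ",
                    as.character(utils::packageVersion("presynATP"))),
      terminal = list(name = p$name, synthetic = p$synthetic,
                      n_atp = as.list(p$n_atp), tau = as.list(p$tau),
                      base_rate_mM_s = p$base_rate, volume_um3 = p$volume,
                      mito_density_pct = p$mito_density,
                      max_rate_per_density = p$max_rate_per_density),
      protocol = list(rate_hz = pr$rate, duty_s = pr$duty,
                      full_cycle_s = pr$full_cycle, n_cycles = pr$n_cycles),
      dt_s = attr(result, "dt"), record_dt_s = attr(result, "record_dt"),
      phosphagen = attr(result, "phosphagen"),
      engine = attr(result, "engine"))
    yaml::write_yaml(meta, metadata_path)
  }
  invisible(path)
}
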