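#' Read a model configuration from YAML
#'
#' One document per terminal: a `terminal` block (per-AP costs, decay
#' constants, base rate, volume, mitochondrial density, production cap
#' preset), plus optional `initial_conditions`, `equilibrium_constants`,
#' `thermo`, `production` (turnover parameters) and `protocol` blocks. Any
#' block left out falls back to the package defaults (the printed literature
#' values for constants; the synthetic terminal for parameters). The default
#' configuration shipped with the package is at
#' `system.file("extdata", "default-config.yaml", package = "presynATP")`.
#'
#' @param path Path to a YAML file.
#' @return List with elements `terminal`, `ic`, `k`, `thermo`, `turnover`,
#'   `cap_exponent` and (if present) `protocol`, ready to pass to
#'   [simulate_terminal()].
#' @export
read_terminal_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  term <- if (!is.null(cfg$terminal)) {
    tc <- cfg$terminal
    # YAML 1.1 reads scientific notation without an explicit sign ("1.2e6")
    # as a string, so numeric fields are coerced explicitly
    num <- function(x) {
      x <- unlist(x)
      stats::setNames(as.numeric(x), names(x))
    }
    terminal_params(
      name = tc$name %||% "terminal",
      n_atp = num(tc$n_atp)[COMPONENTS],
      tau = num(tc$tau)[COMPONENTS],
      base_rate = as.numeric(tc$base_rate),
      volume = as.numeric(tc$volume),
      mito_density = as.numeric(tc$mito_density),
      max_rate_per_density = tc$max_rate_per_density %||% 0.154,
      phosphagen_present = tc$phosphagen_present %||% TRUE,
      synthetic = tc$synthetic %||% FALSE)
  } else default_terminal()
  ic <- if (!is.null(cfg$initial_conditions)) {
    do.call(initial_conditions, cfg$initial_conditions)
  } else initial_conditions()
  k <- if (!is.null(cfg$equilibrium_constants)) {
    do.call(equilibrium_constants, cfg$equilibrium_constants)
  } else equilibrium_constants()
  th <- if (!is.null(cfg$thermo)) {
    do.call(thermo_constants, cfg$thermo)
  } else thermo_constants()
  prod_cfg <- cfg$production %||% list()
  turnover <- hill_turnover(k = prod_cfg$hill_k %||% 0.5,
                            h = prod_cfg$hill_h %||% 1)
  out <- list(terminal = term, ic = ic, k = k, thermo = th,
              turnover = turnover,
              cap_exponent = prod_cfg$cap_exponent %||% 5)
  if (!is.null(cfg$protocol)) {
    pc <- cfg$protocol
    out$protocol <- firing_protocol(rate = pc$rate, duty = pc$duty,
                                    full_cycle = pc$full_cycle,
                                    n_cycles = pc$n_cycles %||% 1,
                                    t_start = pc$t_start %||% 0)
  }
  out
}

#' Write a terminal parameter set to YAML
#'
#' @param params A [terminal_params()].
#' @param path Output path.
#' @param ic,k,thermo Optional constants blocks to include.
#' @param seed Optional generator seed recorded alongside the parameters
#'   (metadata only; ignored on read).
#' @return `path`, invisibly.
#' @export
write_terminal_config <- function(params, path, ic = NULL, k = NULL,
                                  thermo = NULL, seed = NULL) {
  cfg <- list(terminal = list(
    name = params$name, n_atp = as.list(params$n_atp),
    tau = as.list(params$tau), base_rate = params$base_rate,
    volume = params$volume, mito_density = params$mito_density,
    max_rate_per_density = params$max_rate_per_density,
    phosphagen_present = params$phosphagen_present,
    synthetic = params$synthetic))
  if (!is.null(ic)) cfg$initial_conditions <- unclass(ic)
  if (!is.null(k)) cfg$equilibrium_constants <- unclass(k)
  if (!is.null(thermo)) cfg$thermo <- unclass(thermo)
  if (!is.null(seed)) cfg$seed <- seed
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
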