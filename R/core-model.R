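#' @useDynLib presynATP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median coef lm nls runif rnorm sd
NULL

# 1 mM = 6.02214076e5 molecules per cubic micron, so a count of ATP molecules
# in a terminal of volume V um^3 converts to mM as count / (V * 6.02214076e5).
MOLECULES_PER_UM3_PER_MM <- 6.02214076e5

#' Convert a molecule count per terminal to a concentration
#'
#' @param molecules Number of molecules.
#' @param volume_um3 Terminal volume in cubic microns.
#' @return Concentration in mM.
#' @export
molecules_to_mM <- function(molecules, volume_um3) {
  stopifnot(volume_um3 > 0)
  molecules / (volume_um3 * MOLECULES_PER_UM3_PER_MM)
}

#' Metabolic state of a presynaptic terminal
#'
#' The six cytosolic metabolite concentrations tracked by the model, all in mM:
#' ATP, ADP, AMP, arginine (Arg), phosphoarginine (ArgP) and inorganic
#' phosphate (Pi). ArgP is the phosphagen; in vertebrate terms it plays the
#' role of phosphocreatine.
#'
#' @param atp,adp,amp,arg,argp,pi_ Concentrations in mM, all non-negative.
#' @return An object of class `metabolic_state` (named numeric vector).
#' @export
metabolic_state <- function(atp, adp, amp, arg, argp, pi_) {
  x <- c(atp = atp, adp = adp, amp = amp, arg = arg, argp = argp, pi = pi_)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("all concentrations must be finite and non-negative", call. = FALSE)
  }
  structure(x, class = "metabolic_state")
}

#' @export
print.metabolic_state <- function(x, ...) {
  cat("<metabolic_state> (mM)\n")
  print(format(unclass(x), digits = 6), quote = FALSE)
  invisible(x)
}

#' Conserved pools of a metabolic state
#'
#' Equilibration by adenylate kinase and arginine kinase leaves three linear
#' combinations unchanged: the adenine pool ATP+ADP+AMP, the guanidino pool
#' Arg+ArgP, and the phosphoryl tally 3 ATP + 2 ADP + AMP + ArgP.
#'
#' @param state A [metabolic_state()].
#' @return Named numeric vector with elements `adenine`, `guanidino`,
#'   `phosphoryl`.
#' @export
conserved_pools <- function(state) {
  c(adenine = unname(state["atp"] + state["adp"] + state["amp"]),
    guanidino = unname(state["arg"] + state["argp"]),
    phosphoryl = unname(3 * state["atp"] + 2 * state["adp"] +
                          state["amp"] + state["argp"]))
}

#' Equilibrium constants for the two phosphotransfer reactions
#'
#' @param k_ad Adenylate kinase constant for AMP + ATP <-> 2 ADP
#'   (K_Ad = \[ADP\]^2 / (\[ATP\]\[AMP\])). Default 1.
#' @param k_ph Arginine kinase constant for ADP + ArgP <-> ATP + Arg
#'   (K_Ph = \[ATP\]\[Arg\] / (\[ADP\]\[ArgP\])). Default 39.6.
#' @return An object of class `equilibrium_constants`.
#' @export
equilibrium_constants <- function(k_ad = 1, k_ph = 39.6) {
  if (!is.finite(k_ad) || !is.finite(k_ph) || k_ad <= 0 || k_ph <= 0) {
    stop("equilibrium constants must be positive", call. = FALSE)
  }
  structure(list(k_ad = k_ad, k_ph = k_ph), class = "equilibrium_constants")
}

#' Thermodynamic constants for the ATP hydrolysis free energy
#'
#' Defaults: standard free energy of ATP hydrolysis -30.6 kJ/mol, gas constant
#' 8.31445e-3 kJ/mol/K, temperature 300 K. Concentrations entering the
#' logarithm are in mM by convention (see [free_energy()]).
#'
#' @param delta_g0 Standard free energy (kJ/mol, negative).
#' @param gas_constant kJ/mol/K.
#' @param temperature K, positive.
#' @return An object of class `thermo_constants`.
#' @export
thermo_constants <- function(delta_g0 = -30.6,
                             gas_constant = 8.31445e-3,
                             temperature = 300) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  structure(list(delta_g0 = delta_g0, gas_constant = gas_constant,
                 temperature = temperature),
            class = "thermo_constants")
}

#' Initial metabolite concentrations
#'
#' Resting cytosolic concentrations from which the equilibrium starting state
#' is derived. Defaults are the squid-axon literature values used by the
#' model: 2.16 mM ATP, 7.5 mM ArgP, 3.3 mM Arg and 3.8 mM Pi (the low end of
#' the measured 3.8-17.8 mM axonal range, appropriate for terrestrial insect
#' tissue).
#'
#' @param atp0,argp0,pi0 Concentrations in mM, strictly positive.
#' @param arg0 Concentration in mM, non-negative (zero is allowed and yields
#'   zero free ADP and AMP at equilibrium).
#' @return An object of class `initial_conditions`.
#' @export
initial_conditions <- function(atp0 = 2.16, argp0 = 7.5, arg0 = 3.3,
                               pi0 = 3.8) {
  vals <- c(atp0 = atp0, argp0 = argp0, arg0 = arg0, pi0 = pi0)
  if (any(!is.finite(vals))) stop("initial concentrations must be finite",
                                  call. = FALSE)
  if (atp0 <= 0 || argp0 <= 0 || pi0 <= 0 || arg0 < 0) {
    stop("initial concentrations must be positive (arg0 may be zero)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "initial_conditions")
}

#' Equilibrium starting state from resting concentrations
#'
#' Free ADP and AMP are not taken from measurements but derived from the two
#' kinase equilibria: the arginine-kinase relation gives
#' \[ADP\] = \[ATP\]\[Arg\] / (K_Ph \[ArgP\]), and the adenylate-kinase
#' relation then gives \[AMP\] = \[ADP\]^2 / (K_Ad \[ATP\]).
#'
#' With the default constants this yields 0.0240 mM ADP and 0.27 uM AMP.
#'
#' @param ic An [initial_conditions()].
#' @param k An [equilibrium_constants()].
#' @return A [metabolic_state()] satisfying both equilibrium relations.
#' @export
initial_state_from_equilibrium <- function(ic = initial_conditions(),
                                           k = equilibrium_constants()) {
  stopifnot(inherits(ic, "initial_conditions"),
            inherits(k, "equilibrium_constants"))
  adp <- ic$atp0 * ic$arg0 / (k$k_ph * ic$argp0)
  amp <- adp^2 / (k$k_ad * ic$atp0)
  metabolic_state(atp = ic$atp0, adp = adp, amp = amp,
                  arg = ic$arg0, argp = ic$argp0, pi_ = ic$pi0)
}

#' Free energy of ATP hydrolysis
#'
#' Computes dG = dG0 + R T ln(\[ADP\]\[Pi\]/\[ATP\]) with all concentrations in
#' mM inside the logarithm (the convention under which the default resting
#' state gives a magnitude of 38 kJ/mol). The value returned is signed
#' (negative under physiological conditions); the "free energy available" is
#' its magnitude, `abs(free_energy(...))`.
#'
#' @param state A [metabolic_state()] with positive atp, adp and pi.
#' @param th A [thermo_constants()].
#' @return Free energy in kJ/mol (signed).
#' @export
free_energy <- function(state, th = thermo_constants()) {
  atp <- state[["atp"]]; adp <- state[["adp"]]; pi_ <- state[["pi"]]
  if (atp <= 0 || adp <= 0 || pi_ <= 0) {
    stop("free_energy requires positive atp, adp and pi", call. = FALSE)
  }
  th$delta_g0 + th$gas_constant * th$temperature * log(adp * pi_ / atp)
}

#' Energy state
#'
#' The regulatory signal driving ATP production:
#' ES = \[ATP\] / (\[ADP\]\[Pi\]), in 1/mM.
#'
#' @param state A [metabolic_state()] with positive adp and pi.
#' @return Energy state in 1/mM.
#' @export
energy_state <- function(state) {
  adp <- state[["adp"]]; pi_ <- state[["pi"]]
  if (adp <= 0 || pi_ <= 0) {
    stop("energy_state requires positive adp and pi", call. = FALSE)
  }
  state[["atp"]] / (adp * pi_)
}
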