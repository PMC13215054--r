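---
title: "Methods: the presynATP model, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the presynATP model, parameters and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynATP)
```

# Scope

This vignette documents the model implemented by `presynATP`, every
parameter with units, defaults and rationale, the numerical design choices,
and the scope of the synthetic-data generators. It is the package's methods
reference; the README gives the quick tour.

# State and conserved pools

The terminal is a single well-mixed compartment with six concentrations in
mM: `atp`, `adp`, `amp`, `arg` (free arginine), `argp` (phosphoarginine) and
`pi` (inorganic phosphate). Three linear combinations are conserved by every
model operation except consumption/production of ATP (which exchanges ATP
with ADP + Pi and therefore conserves them too):

* adenine pool: [ATP] + [ADP] + [AMP]
* guanidino pool: [Arg] + [ArgP]
* phosphoryl tally: 3[ATP] + 2[ADP] + [AMP] + [ArgP] + [Pi]

`conserved_pools()` evaluates them; the test suite asserts conservation to
a relative 1e-10 through every simulation.

# The resting state

`initial_state_from_equilibrium()` builds the resting state from printed
constants: [ATP] = 2.16 mM, [ArgP] = 7.5 mM, [Arg] = 3.3 mM,
[Pi] = 3.8 mM (classical squid-axoplasm values), with the two kinase
relations solved in closed form:

* [ADP] = [ATP][Arg] / (K_Ph [ArgP]) = 0.024 mM with K_Ph = 39.6,
* [AMP] = [ADP]² / (K_Ad [ATP]) = 0.000267 mM with K_Ad = 1.

The resting energy state is ES = [ATP]/([ADP][Pi]) ≈ 23.7 mM⁻¹ and the
resting free energy ΔG = ΔG₀ + RT ln([ADP][Pi]/[ATP]) = −38.49 kJ/mol with
ΔG₀ = −30.6 kJ/mol, R = 8.31445e-3 kJ/mol/K, T = 300 K. Concentrations enter
the logarithm in mM; this convention is part of the model definition (the
constants were fitted under it) and is asserted by the acceptance tests.

# Firing protocols and consumption

`firing_protocol(rate, duty, full_cycle, n_cycles, t_start)` describes
cyclical stimulation: `rate` Hz firing for the first `duty` seconds of every
`full_cycle`-second cycle. Spike times within a cycle are k/rate for
k = 0, 1, … while k/rate ≤ duty — an inclusive-endpoint convention, so
10 Hz over a 0.6 s duty yields 7 spikes (k = 0..6), the 42 Hz × 0.8 s × 240
locomotion protocol yields 8160 action potentials and the 50 Hz × 2 s × 60
Ca²⁺-pumping protocol 6060. A 1e-9 s guard absorbs floating-point error at
the boundary. Presets: `locomotion`, `ca_pumping`, `train60` (60 Hz, 30
APs), `train80` (80 Hz, 10 s).

Each action potential at time t_s commits `n_atp[j]` ATP molecules to cost
component j ∈ {Na, Ca, NT1, NT2, NT3}, spent at rate
(N_j/τ_j)·exp((t_s − t)/τ_j) for t ≥ t_s. Total consumption is

c(t) = base_rate + Σ_spikes Σ_j (N_j/τ_j)·exp((t_s − t)/τ_j)  (mM/s),

with molecule counts converted by 1 mM = 6.02214076e5 molecules/µm³ over the
terminal volume. `integrated_cost()` gives the closed-form integral used as
an oracle for the numerical accumulator.

# Production

Production responds to the energy state through a relative turnover curve
`pcc(ES)`, normalized at rest:

p(ES) = base_rate · pcc(ES) / pcc(ES_rest),

so the resting state is exactly balanced (production = base consumption).
Physiologically the oxidative machinery runs faster when energy is low, so
pcc must be **decreasing** in ES; the default is the Hill-type form
pcc(ES) = 1 / (1 + (ES/k)^h) with k = 0.5 mM⁻¹ and h = 1. With
ES_rest ≈ 23.7 mM⁻¹ this leaves roughly 50-fold headroom: production can
rise steeply as ES falls during stimulation. k and h are model choices, not
measured values; any positive decreasing turnover function can be supplied
(`production_model_for(..., turnover = )`; custom R closures run on the
reference engine).

The rate is saturated by the soft cap

p_capped = (p⁻⁵ + p_max⁻⁵)^(−1/5),

which approaches min(p, p_max) but is smooth. p_max = cap preset ×
mitochondrial density (% of terminal volume); presets 0.079 and
0.154 mM/s per 1 % density are the two literature estimates, switchable via
the CLI `--cap {low,high}` flag or `max_rate_per_density`.

# Equilibration

`equilibrate()` projects a state onto the manifold where

K_Ad [ATP][AMP] = [ADP]²  and  K_Ph [ADP][ArgP] = [ATP][Arg]

by solving for two reaction extents — x for adenylate kinase
(AMP + ATP → 2 ADP) and y for arginine kinase (ADP + ArgP → ATP + Arg) —
which conserves all three pools by construction and leaves Pi untouched
(the phosphoryl moves between ArgP and the adenine nucleotides).

The solver is a damped two-variable Newton iteration on the residuals with
an analytic Jacobian; steps must stay in the non-negative orthant and reduce
the residual, halving otherwise. Whenever Newton stalls, a nested bisection
brackets the physical root: for each y the adenylate-kinase relation is
solved for x by bisection, and the arginine-kinase residual at (x(y), y) is
scanned for a strict sign change over the feasible y-range. The strictness
matters: the algebraic system has vacuous boundary roots (e.g.
[ATP] = [ADP] = 0 satisfies both relations as 0 = 0) that are not chemical
equilibria of an interior state; the solver rejects any converged state on
such a boundary when the input was interior, and the nested bisection cannot
land on one. Convergence is declared at a relative residual of 1e-10
(`equilibration_options()`), each residual scaled by the larger of its two
sides. With `enforce_phosphagen = FALSE` only the adenylate-kinase relation
is solved, modelling the phosphagen-removed condition.

Inside a simulation the state starts each step close to the manifold, so
Newton typically converges in one or two iterations; the bisection path is
exercised by far-from-equilibrium inputs (and by the test suite's randomized
states, cross-checked against an independent brute-force oracle to 1e-8).

# Time stepping

`simulate_terminal()` advances the state with first-order operator
splitting per step of length dt:

1. spikes scheduled in (t, t+dt] are deposited at the nearest grid point
   (each spike adds N_j/τ_j to an exponentially decaying accumulator per
   component; the accumulator is decayed by exp(−dt/τ_j) each step, which
   integrates the consumption kernel exactly between deposits);
2. ATP changes by dt·(production − consumption), with ADP and Pi changing
   oppositely;
3. the state is re-equilibrated.

If a step would drive ATP, ADP or Pi negative, that step alone is subdivided
into up to 2¹⁰ equal substeps; if even that fails the simulation stops with
an informative error (this is the expected outcome of a genuine exhaustion
scenario, e.g. heavy drive with production disabled).

Defaults: dt = 1e-4 s, recording every `record_dt` = 0.05 s (`record_dt`
must be a multiple of dt). These are the package's own choices: at dt = 1e-4
the dt-halving change in recorded [ATP] is far below 0.1 % (asserted by
test), and the full 20-minute locomotion protocol (12 million steps)
integrates in well under 2 minutes on one CPU via the compiled loop. The
scheme is first order; the convergence tests verify the error roughly halves
when dt halves.

Two engines implement the identical scheme: the compiled loop
(`src/simulate_loop.cpp`) and a plain-R reference (`engine = "r"`). They are
independent implementations and agree to ~1e-15 relative on short runs
(asserted by test); the R engine is the oracle for the C++ one.

# Trace analysis

* `trace_ratio()`: per-frame background subtraction (mean over background
  regions, per channel), then the channel ratio R = num/den.
* `bleach_correct()`: fits a·exp(−t/τ) + c (offset optional) to the 20 s of
  pre-stimulus ratio by Levenberg–Marquardt (`minpack.lm::nls.lm`,
  initialized from a log-linear regression), divides the ratio by the fit
  over the correction window (−10 to +40 s around stimulus onset by
  default), and rescales the window so its pre-stimulus mean is 1. Samples
  outside the window are returned unchanged. A perfectly flat baseline is
  normalized directly (τ = ∞). A failed fit returns the series uncorrected
  with `converged = FALSE` and a warning rather than an error.
* `delta_r_over_r()`: ΔR/R = (R − R_rest)/R_rest with R_rest the
  pre-stimulus mean (restricted to the corrected window when bleach
  correction is applied).
* `mad_outlier_flags()`: flags values outside median ± 3·MAD where MAD is
  the **unscaled** median absolute deviation (no 1.4826 consistency
  constant); bounds are inclusive (values exactly on a bound are kept).
* `quantal_content()`: mean EJP corrected for non-linear summation as
  v/(1 − v/driving) (unit correction factor, driving force in mV, no
  default — it must be supplied), divided by the mean mEJP; miniatures are
  never corrected.

# Synthetic data

No per-terminal measurements are published for the consumption parameters,
so the package generates clearly labelled synthetic data
(`generator_spec(seed)` fixes everything; generators never disturb the
global RNG stream):

* `gen_terminal_params()` / `default_terminal()`: per-AP molecule counts
  (order 10⁵–10⁶ per component), decay constants spanning 0.1–15 s, base
  rate 0.02 mM/s, volume 400 µm³, mitochondrial density 5–7 %. The default
  terminal is the range midpoint, calibrated **once** so that the resting
  state is a steady state and sustained locomotion drive survives both cap
  presets; it was not tuned to any quantitative target.
* `gen_ratiometric_trace()`: two-channel trace with common-mode
  monoexponential bleach (default τ = 100 s), a programmed response of known
  peak ΔR/R (default 0.3) in the numerator channel, Gaussian noise, and
  constant backgrounds; ground truth is in the spec.
* `gen_amplitude_samples()`: mEJP amplitudes (lognormal, known mean and CV)
  and EJP amplitudes built from a known quantal count with the non-linear
  summation applied **forward**, so the analysis pipeline must invert it to
  recover the truth.

# Limitations

* The terminal parameters are synthetic; simulated trajectories illustrate
  the model's qualitative behaviour (phosphagen buffering, cap effects) and
  are not quantitative predictions for any measured terminal.
* The kinase equilibria are enforced instantaneously; finite kinase kinetics
  are outside the model.
* The compartment is well mixed; no spatial gradients, transport or
  per-bouton structure.
* Production is a single lumped oxidative term; glycolysis and adenylate
  salvage beyond adenylate kinase are not modelled.
* The integrator is first order by design (the equilibration projection
  dominates the step); use dt-halving to verify resolution for new
  protocols.
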