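# Default model configuration.
#
# Constants and initial concentrations are the printed literature values
# (squid-axon concentrations; K_Ph 39.6, K_Ad 1; dG0 -30.6 kJ/mol at 300 K).
# The terminal block is SYNTHETIC: per-AP costs, decay constants, base rate
# and volume are plausible stand-ins, not measured values for any terminal.
# Replace this block with a measured parameter set if you hold one.
terminal:
  name: synthetic-Ib
  synthetic: true
  n_atp:           # ATP molecules consumed per action potential
    Na: 1.2e+6
    Ca: 0.7e+6
    NT1: 0.5e+6
    NT2: 0.4e+6
    NT3: 0.3e+6
  tau:             # decay constants, s
    Na: 0.1
    Ca: 0.3
    NT1: 1.05
    NT2: 4.5
    NT3: 15.0
  base_rate: 0.02          # non-signalling consumption, mM/s
  volume: 400              # terminal volume, um^3
  mito_density: 6.0        # mitochondrial volume density, %
  max_rate_per_density: 0.154  # production cap preset, mM/s per 1% (alt: 0.079)
  phosphagen_present: true
initial_conditions:
  atp0: 2.16   # mM
  argp0: 7.5   # mM
  arg0: 3.3    # mM
  pi0: 3.8     # mM
equilibrium_constants:
  k_ad: 1.0
  k_ph: 39.6
thermo:
  delta_g0: -30.6          # kJ/mol
  gas_constant: 8.31445e-3 # kJ/mol/K
  temperature: 300         # K
production:
  hill_k: 0.5   # half-maximal energy state, 1/mM
  hill_h: 1.0   # Hill exponent
  cap_exponent: 5
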