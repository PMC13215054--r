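test_that("equilibrium initial state reproduces the closed-form relations", {
  s <- initial_state_from_equilibrium(initial_conditions(), # printed defaults
                                      equilibrium_constants())
  # ADP from the arginine-kinase relation, AMP from the adenylate-kinase one
  expect_equal(s[["adp"]], 2.16 * 3.3 / (39.6 * 7.5), tolerance = 1e-14)
  expect_equal(s[["amp"]], s[["adp"]]^2 / 2.16, tolerance = 1e-14)
  # rounds to the 0.024 mM / 0.27 uM figures
  expect_equal(round(s[["adp"]], 3), 0.024)
  expect_equal(round(s[["amp"]] * 1000, 2), 0.27)
  # both equilibrium relations satisfied to 1e-12 relative
  expect_lt(abs(1 * s[["atp"]] * s[["amp"]] - s[["adp"]]^2) / s[["adp"]]^2,
            1e-12)
  expect_lt(abs(39.6 * s[["adp"]] * s[["argp"]] - s[["atp"]] * s[["arg"]]) /
              (s[["atp"]] * s[["arg"]]), 1e-12)
})

test_that("equilibrium initial state matches hand-evaluated cases", {
  s <- initial_state_from_equilibrium(
    initial_conditions(atp0 = 2, argp0 = 5, arg0 = 5, pi0 = 3.8),
    equilibrium_constants(k_ad = 1, k_ph = 40))
  expect_equal(s[["adp"]], 0.05, tolerance = 1e-14)
  expect_equal(s[["amp"]], 0.00125, tolerance = 1e-14)

  # zero free arginine gives zero free ADP and AMP
  s0 <- initial_state_from_equilibrium(initial_conditions(arg0 = 0))
  expect_identical(s0[["adp"]], 0)
  expect_identical(s0[["amp"]], 0)

  expect_error(initial_conditions(atp0 = -1), "positive")
  expect_error(initial_conditions(argp0 = 0), "positive")
})

test_that("the derived initial state is a fixed point of equilibration", {
  s <- initial_state_from_equilibrium()
  s2 <- equilibrate(s)
  expect_lt(max(rel_diff(unclass(s2), unclass(s))), 1e-10)
})

test_that("free energy follows the mM-convention formula", {
  th <- thermo_constants()
  # [ADP][Pi]/[ATP] = 1 mM makes the log vanish
  s1 <- metabolic_state(atp = 2, adp = 0.5, amp = 0, arg = 1, argp = 1,
                        pi_ = 4)
  expect_equal(free_energy(s1, th), -30.6, tolerance = 1e-12)

  # resting state: 38 kJ/mol available to the nearest integer
  s <- initial_state_from_equilibrium()
  expect_equal(round(abs(free_energy(s, th))), 38)

  # doubling adp and halving atp at fixed pi shifts dG by +RT ln 4
  s_mod <- metabolic_state(atp = s[["atp"]] / 2, adp = 2 * s[["adp"]],
                           amp = s[["amp"]], arg = s[["arg"]],
                           argp = s[["argp"]], pi_ = s[["pi"]])
  expect_equal(free_energy(s_mod, th) - free_energy(s, th),
               th$gas_constant * th$temperature * log(4), tolerance = 1e-12)

  s_bad <- metabolic_state(atp = 1, adp = 0, amp = 0, arg = 1, argp = 1,
                           pi_ = 1)
  expect_error(free_energy(s_bad, th), "positive")
})

test_that("energy state is ATP/(ADP*Pi) with the expected arithmetic", {
  s <- metabolic_state(atp = 2.16, adp = 0.0242, amp = 0, arg = 0, argp = 0,
                       pi_ = 3.8)
  expect_equal(energy_state(s), 2.16 / (0.0242 * 3.8), tolerance = 1e-14)
  expect_equal(round(energy_state(s), 1), 23.5)

  s_one <- metabolic_state(atp = 0.5 * 4, adp = 0.5, amp = 0, arg = 0,
                           argp = 0, pi_ = 4)
  expect_equal(energy_state(s_one), 1)

  s_half <- metabolic_state(atp = s[["atp"]] / 2, adp = 0.0242, amp = 0,
                            arg = 0, argp = 0, pi_ = 3.8)
  expect_equal(energy_state(s_half), energy_state(s) / 2, tolerance = 1e-14)

  expect_error(energy_state(metabolic_state(1, 0, 0, 0, 0, 1)), "positive")
})

test_that("free energy is monotone in each concentration and consistent with ES", {
  th <- thermo_constants()
  set.seed(7)
  for (i in 1:50) {
    s <- random_state()
    up_adp <- metabolic_state(s[["atp"]], s[["adp"]] * 1.2, s[["amp"]],
                              s[["arg"]], s[["argp"]], s[["pi"]])
    up_pi <- metabolic_state(s[["atp"]], s[["adp"]], s[["amp"]],
                             s[["arg"]], s[["argp"]], s[["pi"]] * 1.2)
    up_atp <- metabolic_state(s[["atp"]] * 1.2, s[["adp"]], s[["amp"]],
                              s[["arg"]], s[["argp"]], s[["pi"]])
    expect_gt(free_energy(up_adp, th), free_energy(s, th))
    expect_gt(free_energy(up_pi, th), free_energy(s, th))
    expect_lt(free_energy(up_atp, th), free_energy(s, th))
    # dG = dG0 - RT ln(ES), ES in 1/mM
    expect_equal(free_energy(s, th),
                 th$delta_g0 - th$gas_constant * th$temperature *
                   log(energy_state(s)),
                 tolerance = 1e-12)
  }
})

test_that("metabolic state validates and reports conserved pools", {
  expect_error(metabolic_state(-1, 0, 0, 0, 0, 1), "non-negative")
  s <- metabolic_state(2, 0.1, 0.01, 3, 7, 4)
  p <- conserved_pools(s)
  expect_equal(unname(p["adenine"]), 2.11)
  expect_equal(unname(p["guanidino"]), 10)
  expect_equal(unname(p["phosphoryl"]), 3 * 2 + 2 * 0.1 + 0.01 + 7)
})

test_that("molecule counts convert to mM via Avogadro and terminal volume", {
  # 1 mM in 1 um^3 corresponds to 6.02214076e5 molecules
  expect_equal(molecules_to_mM(6.02214076e5, 1), 1, tolerance = 1e-12)
  expect_equal(molecules_to_mM(1.2e6, 400), 1.2e6 / (400 * 6.02214076e5))
})
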