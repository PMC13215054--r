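# terminal whose APs carry no cost: consumption is the constant base rate
quiet_terminal <- function(...) {
  default_terminal(n_atp = c(Na = 0, Ca = 0, NT1 = 0, NT2 = 0, NT3 = 0), ...)
}

test_that("a zero-dt step is the identity and balanced fluxes hold the state", {
  s <- initial_state_from_equilibrium()
  expect_equal(unclass(step_state(s, 0, 0.5, 0.2)), unclass(s),
               tolerance = 1e-15)
  s2 <- step_state(s, 1e-3, consumption = 0.02, production = 0.02)
  expect_lt(max(rel_diff(unclass(s2), unclass(s))), 1e-10)
  expect_error(step_state(s, 10, consumption = 1, production = 0),
               "negative")
})

test_that("the calibrated rest state is a steady state of the simulation", {
  tp <- quiet_terminal()
  pr <- firing_protocol(rate = 1, duty = 0, full_cycle = 1, n_cycles = 20)
  r <- simulate_terminal(tp, pr, dt = 1e-3, record_dt = 0.1)
  s0 <- initial_state_from_equilibrium()
  for (v in c("atp", "adp", "amp", "arg", "argp", "pi")) {
    expect_lt(max(rel_diff(r[[v]], s0[[v]])), 1e-9)
  }
})

test_that("with production off and no equilibration ATP decays linearly", {
  tp <- quiet_terminal(base_rate = 0.05)
  pr <- firing_protocol(rate = 1, duty = 0, full_cycle = 1, n_cycles = 10)
  r <- simulate_terminal(tp, pr, dt = 1e-3, record_dt = 0.1,
                         production = FALSE, equil = NULL)
  s0 <- initial_state_from_equilibrium()
  expect_equal(r$atp, s0[["atp"]] - 0.05 * r$time, tolerance = 1e-9)
  expect_equal(r$adp, s0[["adp"]] + 0.05 * r$time, tolerance = 1e-9)
})

test_that("compiled and reference engines produce the same trajectory", {
  tp <- default_terminal()
  pr <- firing_protocol(rate = 42, duty = 0.8, full_cycle = 1, n_cycles = 3)
  rc <- simulate_terminal(tp, pr, dt = 2e-4, record_dt = 0.02)
  rr <- simulate_terminal(tp, pr, dt = 2e-4, record_dt = 0.02, engine = "r")
  for (v in c("atp", "adp", "amp", "arg", "argp", "pi", "consumption",
              "production")) {
    expect_lt(max(rel_diff(rc[[v]], rr[[v]])), 1e-9)
  }
})

test_that("halving dt changes ATP by <0.1% and the scheme is first order", {
  tp <- default_terminal()
  # 50 Hz spikes fall on all three grids
  pr <- firing_protocol(rate = 50, duty = 2, full_cycle = 4, n_cycles = 2)
  r1 <- simulate_terminal(tp, pr, dt = 4e-4, record_dt = 0.1)
  r2 <- simulate_terminal(tp, pr, dt = 2e-4, record_dt = 0.1)
  r3 <- simulate_terminal(tp, pr, dt = 1e-4, record_dt = 0.1)
  expect_lt(max(rel_diff(r2$atp, r1$atp)), 1e-3)
  d12 <- max(abs(r1$atp - r2$atp))
  d23 <- max(abs(r2$atp - r3$atp))
  expect_gt(d12 / d23, 1.4)  # halving dt roughly halves the error
  expect_lt(d12 / d23, 3.5)
})

test_that("mass balance holds across a stimulated simulation", {
  tp <- default_terminal()
  pr <- firing_protocol(rate = 42, duty = 0.8, full_cycle = 1, n_cycles = 10)
  r <- simulate_terminal(tp, pr, dt = 1e-4, record_dt = 0.05)
  adenine <- r$atp + r$adp + r$amp
  guanidino <- r$arg + r$argp
  total_p <- 3 * r$atp + 2 * r$adp + r$amp + r$argp + r$pi
  expect_lt(max(rel_diff(adenine, adenine[1])), 1e-9)
  expect_lt(max(rel_diff(guanidino, guanidino[1])), 1e-9)
  expect_lt(max(rel_diff(total_p, total_p[1])), 1e-9)
})

test_that("removing the phosphagen raises volatility and deepens ATP/ADP minima", {
  tp <- default_terminal()
  pr <- firing_protocol(rate = 42, duty = 0.8, full_cycle = 1, n_cycles = 30)
  cmp <- compare_phosphagen(tp, pr, dt = 2e-4, record_dt = 0.01)
  v_on <- simulation_volatility(cmp$with)
  v_off <- simulation_volatility(cmp$without)
  expect_gt(v_off$mean_peak_to_trough, v_on$mean_peak_to_trough)
  expect_gt(v_off$sd_detrended, v_on$sd_detrended)
  expect_gte(min(cmp$with$atp_adp), min(cmp$without$atp_adp))
  # buffering never lowers the time-averaged ATP, and both runs stay positive
  expect_gte(mean(cmp$with$atp), mean(cmp$without$atp))
  expect_true(all(cmp$without$atp > 0))
})

test_that("raising the production cap weakly increases ATP pointwise", {
  pr <- firing_protocol(rate = 42, duty = 0.8, full_cycle = 1, n_cycles = 30)
  lo <- simulate_terminal(default_terminal(max_rate_per_density = 0.079), pr,
                          dt = 2e-4, record_dt = 0.02)
  hi <- simulate_terminal(default_terminal(max_rate_per_density = 0.154), pr,
                          dt = 2e-4, record_dt = 0.02)
  expect_true(all(hi$atp >= lo$atp - 1e-12))
})

test_that("overload without production fails with a step-size error", {
  tp <- quiet_terminal(base_rate = 1)
  pr <- firing_protocol(rate = 1, duty = 0, full_cycle = 1, n_cycles = 5)
  expect_error(simulate_terminal(tp, pr, dt = 1e-3, record_dt = 0.1,
                                 production = FALSE, equil = NULL),
               "negative")
})

test_that("action potential counts follow the printed protocols", {
  expect_identical(count_action_potentials(protocol_preset("ca_pumping")),
                   6060L)
  expect_identical(count_action_potentials(protocol_preset("locomotion")),
                   8160L)
  expect_identical(count_action_potentials(
    firing_protocol(rate = 30, duty = 0, full_cycle = 1, n_cycles = 5)), 5L)
  expect_identical(count_action_potentials(protocol_preset("train60")), 30L)
})

test_that("volatility summarizes per-cycle excursions", {
  t <- seq(0, 5, by = 0.001)
  v_const <- volatility(rep(1, length(t)), t, cycle_length = 1)
  expect_equal(v_const$mean_peak_to_trough, 0)
  expect_equal(v_const$sd_detrended, 0, tolerance = 1e-12)

  s <- sin(2 * pi * t)
  v_sin <- volatility(s, t, cycle_length = 1)
  expect_equal(v_sin$mean_peak_to_trough, 2, tolerance = 1e-4)
})

test_that("results round-trip through the CSV writer", {
  tp <- default_terminal()
  pr <- firing_protocol(rate = 10, duty = 0.2, full_cycle = 1, n_cycles = 2)
  r <- simulate_terminal(tp, pr, dt = 1e-3, record_dt = 0.1)
  csv <- tempfile(fileext = ".csv"); meta <- tempfile(fileext = ".yaml")
  write_simulation_csv(r, csv, metadata_path = meta)
  back <- read.csv(csv)
  expect_equal(back$atp_mM, r$atp)
  expect_equal(back$dG_kJ_mol, r$free_energy)
  m <- yaml::read_yaml(meta)
  expect_true(m$terminal$synthetic)
  expect_equal(m$dt_s, 1e-3)
})

test_that("configurations round-trip through YAML", {
  cfg_path <- system.file("extdata", "default-config.yaml",
                          package = "presynATP")
  cfg <- read_terminal_config(cfg_path)
  expect_s3_class(cfg$terminal, "terminal_params")
  expect_equal(cfg$ic$atp0, 2.16)
  expect_equal(cfg$k$k_ph, 39.6)
  expect_equal(cfg$thermo$delta_g0, -30.6)
  tmp <- tempfile(fileext = ".yaml")
  write_terminal_config(cfg$terminal, tmp, ic = cfg$ic, k = cfg$k)
  cfg2 <- read_terminal_config(tmp)
  expect_equal(cfg2$terminal$n_atp, cfg$terminal$n_atp)
  expect_equal(cfg2$ic$pi0, cfg$ic$pi0)
})
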