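flat_trace <- function(n = 200, dt = 0.25, stim = 20,
                       num = 1000, den = 800, bg = 100) {
  time <- seq(0, by = dt, length.out = n)
  ratiometric_trace(time = time,
                    signal_num = rep(num, n), signal_den = rep(den, n),
                    background_num = rep(bg, n), background_den = rep(bg, n),
                    stim_start = stim, stim_end = stim + 10)
}

test_that("constant channels give identically zero dR/R", {
  expect_equal(unname(delta_r_over_r(flat_trace())), rep(0, 200),
               ignore_attr = TRUE)
})

test_that("a doubling numerator steps dR/R from 0 to +1", {
  tr <- flat_trace()
  on <- tr$time >= tr$stim_start
  tr$signal_num[on] <- 100 + 2 * (1000 - 100)  # background-corrected doubling
  d <- delta_r_over_r(tr)
  expect_equal(unname(d[!on]), rep(0, sum(!on)), ignore_attr = TRUE)
  expect_equal(unname(d[on]), rep(1, sum(on)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("dR/R is invariant to common-mode gain", {
  spec <- generator_spec(seed = 21, noise_sd = 0)
  tr <- gen_ratiometric_trace(spec)
  d1 <- delta_r_over_r(tr)
  g <- 3.7
  tr2 <- ratiometric_trace(tr$time, g * tr$signal_num, g * tr$signal_den,
                           g * tr$background_num, g * tr$background_den,
                           tr$stim_start, tr$stim_end)
  d2 <- delta_r_over_r(tr2)
  expect_equal(unname(d2), unname(d1), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("background above signal in the denominator is rejected", {
  tr <- flat_trace(den = 90, bg = 100)
  expect_error(delta_r_over_r(tr), "denominator")
})

test_that("bleach correction is the identity on a flat baseline", {
  time <- seq(-25, 40, by = 0.25)
  ratio <- rep(1.25, length(time))
  out <- bleach_correct(ratio, time, stim_start = 0)
  win <- time >= -10 & time <= 40
  expect_equal(out[win], rep(1, sum(win)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(attr(out, "converged"))
})

test_that("a pure monoexponential bleach is flattened to 1", {
  time <- seq(-25, 40, by = 0.25)
  for (tau in c(40, 120)) {
    ratio <- 1.4 * exp(-(time + 25) / tau)
    out <- bleach_correct(ratio, time, stim_start = 0, offset = FALSE)
    win <- time >= -10 & time <= 40
    expect_equal(out[win], rep(1, sum(win)), tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_equal(attr(out, "tau"), tau, tolerance = 0.01)
  }
})

test_that("a programmed response survives the bleach correction", {
  # deterministic dip on a bleaching baseline
  time <- seq(-25, 40, by = 0.25)
  dip <- ifelse(time >= 0 & time < 10, -0.2, 0)
  ratio <- 1.2 * exp(-(time + 25) / 80) * (1 + dip)
  out <- bleach_correct(ratio, time, stim_start = 0)
  pre <- time >= -10 & time < 0
  during <- time >= 2 & time < 9
  expect_equal(mean(out[during]) / mean(out[pre]) - 1, -0.2,
               tolerance = 1e-3)
})

test_that("generator traces yield the programmed peak after the full pipeline", {
  for (tau_b in c(50, 150)) {
    for (noise in c(0.2, 0.6)) {
      spec <- generator_spec(seed = 100 + round(tau_b + noise * 10),
                             tau_bleach = tau_b, noise_sd = noise,
                             response_amplitude = 0.3)
      tr <- gen_ratiometric_trace(spec)
      d <- delta_r_over_r(tr, bleach = TRUE)
      pre <- tr$time < 0 & tr$time >= -10
      sigma <- sd(d[pre])
      peak <- max(d[tr$time >= 0 & tr$time <= 30])
      expect_lt(abs(peak - 0.3), 3 * sigma + 1e-3)
    }
  }
})

test_that("MAD flags match hand computation and brute force", {
  x <- c(1, 2, 3, 4, 100)  # median 3, MAD 1, bounds [0, 6]
  expect_identical(mad_outlier_flags(x), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(mad_outlier_flags(c(-1, 0, 1)), rep(FALSE, 3))
  # values exactly on a bound are kept
  expect_identical(mad_outlier_flags(c(0, 2, 3, 4, 6)), rep(FALSE, 5))
  expect_identical(mad_outlier_flags(rep(2, 5)), rep(FALSE, 5))
  expect_warning(f <- mad_outlier_flags(c(1, 1, 1, 5)), "MAD is zero")
  expect_identical(f, c(FALSE, FALSE, FALSE, TRUE))

  set.seed(8)
  for (i in 1:50) {
    v <- rnorm(sample(5:60, 1), sd = sample(c(0.1, 1, 10), 1))
    if (runif(1) < 0.3) v <- c(v, 100)
    expect_identical(mad_outlier_flags(v), oracle_mad_flags(v))
  }

  # removing flagged points then re-flagging changes nothing further
  x2 <- x[!mad_outlier_flags(x)]
  expect_identical(mad_outlier_flags(x2), rep(FALSE, length(x2)))
})

test_that("quantal content applies the non-linear summation correction", {
  # small correction, computed by hand: 0.12/(1 - 0.12/120)/0.01
  q <- quantal_content(ejp = rep(0.12, 10), mejp = rep(0.01, 30),
                       driving = 120)
  expect_equal(q$qc, 0.12 / (1 - 0.12 / 120) / 0.01, tolerance = 1e-12)
  expect_equal(q$qc, 12, tolerance = 2e-3)

  # mean EJP at half the driving force doubles the corrected mean
  q2 <- quantal_content(ejp = rep(60, 10), mejp = rep(1, 30), driving = 120)
  expect_equal(q2$corrected_mean_ejp, 120)
  expect_equal(q2$qc, 120)

  # mEJPs equal to the raw mean EJP: QC is exactly the correction factor
  q3 <- quantal_content(ejp = rep(30, 10), mejp = rep(30, 30), driving = 120)
  expect_equal(q3$qc, 1 / (1 - 30 / 120))

  expect_error(quantal_content(rep(130, 5), rep(1, 5), driving = 120),
               "driving")
  expect_error(quantal_content(rep(10, 5), rep(1, 5)), "driving")
})
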