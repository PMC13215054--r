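# Independent brute-force oracles used to cross-check the package solvers.
# Deliberately written with plain loops and no calls into the package
# implementation paths they validate.

# Equilibrate by nested bisection over the two reaction extents:
# outer over the arginine-kinase extent y (grid scan for the sign change,
# then bisection), inner over the adenylate-kinase extent x.
oracle_equilibrate <- function(state, k_ad, k_ph, grid_n = 200) {
  atp0 <- state[["atp"]]; adp0 <- state[["adp"]]; amp0 <- state[["amp"]]
  arg0 <- state[["arg"]]; argp0 <- state[["argp"]]

  x_for <- function(y) {
    lo <- (y - adp0) / 2
    hi <- min(amp0, atp0 + y)
    if (hi <= lo) return((lo + hi) / 2)   # degenerate corner of the range
    for (i in 1:100) {
      m <- (lo + hi) / 2
      f <- k_ad * (atp0 - m + y) * (amp0 - m) - (adp0 + 2 * m - y)^2
      if (f > 0) lo <- m else hi <- m
    }
    (lo + hi) / 2
  }
  g <- function(y) {
    x <- x_for(y)
    k_ph * (adp0 + 2 * x - y) * (argp0 - y) -
      (atp0 - x + y) * (arg0 + y)
  }
  # outer range limited to where the inner AK interval is non-empty:
  # (y - adp0)/2 <= min(amp0, atp0 + y)
  ylo <- max(-arg0, -(2 * atp0 + adp0))
  yhi <- min(argp0, 2 * amp0 + adp0)
  ys <- seq(ylo, yhi, length.out = grid_n)
  gs <- vapply(ys, g, numeric(1))
  # prefer a strict interior crossing, which excludes the degenerate
  # boundary roots where both relations hold as 0 = 0
  cross <- which(gs[-length(gs)] > 0 & gs[-1] < 0)[1]
  if (is.na(cross)) cross <- which(gs[-length(gs)] >= 0 & gs[-1] <= 0)[1]
  if (is.na(cross)) stop("oracle: no sign change found")
  lo <- ys[cross]; hi <- ys[cross + 1]
  for (i in 1:100) {
    m <- (lo + hi) / 2
    if (g(m) > 0) lo <- m else hi <- m
  }
  y <- (lo + hi) / 2
  x <- x_for(y)
  c(atp = atp0 - x + y, adp = adp0 + 2 * x - y, amp = amp0 - x,
    arg = arg0 + y, argp = argp0 - y, pi = state[["pi"]])
}

# Brute-force spike enumeration: loop over cycles and within-cycle indices.
oracle_spike_times <- function(rate, duty, full_cycle, n_cycles, t_start = 0) {
  out <- numeric(0)
  for (c0 in seq_len(n_cycles) - 1) {
    tc <- t_start + c0 * full_cycle
    k <- 0
    while (k / rate <= duty + 1e-9) {
      out <- c(out, tc + k / rate)
      k <- k + 1
    }
  }
  out
}

# Brute-force MAD outlier rule, scalar loop.
oracle_mad_flags <- function(x) {
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) {
    s <- sort(x)
    med <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  }
  dev <- abs(x - med)
  s <- sort(dev)
  mad0 <- if (length(x) %% 2 == 0) {
    (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  } else s[ceiling(length(x) / 2)]
  flags <- logical(length(x))
  for (i in seq_along(x)) {
    flags[i] <- x[i] > med + 3 * mad0 || x[i] < med - 3 * mad0
  }
  flags
}

# Random feasible metabolic state (concentrations away from the degenerate
# boundary, where relative residual checks are well conditioned).
random_state <- function() {
  metabolic_state(atp = runif(1, 0.1, 5), adp = runif(1, 0.01, 1),
                  amp = runif(1, 0.01, 0.5), arg = runif(1, 0.1, 8),
                  argp = runif(1, 0.1, 10), pi_ = runif(1, 0.5, 15))
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
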