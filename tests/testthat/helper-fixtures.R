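# Fixtures are built in code: a deterministic triangle network (1 NO, 3 NP,
# 4 OP two-arm trials) and slow-but-sure bisection oracles for the link
# functions.

triangle_data <- function(m = 5) {
  tibble::tibble(
    trial_id = rep(c("NO_1", "NP_1", "NP_2", "NP_3",
                     "OP_1", "OP_2", "OP_3", "OP_4"), each = 2),
    intervention = c("O", "N", rep(c("P", "N"), 3), rep(c("P", "O"), 4)),
    n = rep(c(150L, 160L, 140L, 120L, 150L, 130L, 170L, 110L), each = 2),
    r_obs = c(95L, 101L, 40L, 61L, 35L, 58L, 42L, 60L,
              45L, 64L, 38L, 52L, 50L, 70L, 33L, 45L),
    m = as.integer(m)
  )
}

triangle_net <- function(m = 5) nma_network(triangle_data(m), reference = "P")

tiny_mcmc <- function(seed = 1, iterations = 900, burn_in = 300, thin = 1) {
  mcmc_options(chains = 2, iterations = iterations, burn_in = burn_in,
               thin = thin, seed = seed)
}

# Bisection root of f on [lo, hi] (f(lo) < 0 < f(hi)), vectorised over inputs.
bisect_vec <- function(f, lo, hi, iters = 80) {
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    neg <- f(mid) < 0
    lo <- ifelse(neg, mid, lo)
    hi <- ifelse(neg, hi, mid)
  }
  (lo + hi) / 2
}

# p_obs solving the pattern-mixture identity, independent of the closed form.
oracle_pm_observed_risk <- function(p, q, phi) {
  f <- function(x) {
    pmis <- stats::plogis(stats::qlogis(x) + phi)
    x * (1 - q) + pmis * q - p
  }
  bisect_vec(f, lo = rep(1e-14, length(p)), hi = rep(1 - 1e-14, length(p)))
}

# c0 solving the selection identity q = c1 p + c0 (1 - p).
oracle_selection_c0 <- function(p, q, phi) {
  d <- exp(phi)
  f <- function(y) {
    c1 <- d * y / (1 + (d - 1) * y)
    c1 * p + y * (1 - p) - q
  }
  bisect_vec(f, lo = rep(0, length(p)), hi = rep(1 - 1e-14, length(p)))
}
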