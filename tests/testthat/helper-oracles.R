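# Independent oracles and small fixtures shared across test files.

# Brute-force bisection of the charge balance over pH in [0, 14] at 1e-6
# resolution, written independently of the package's solver (textbook
# ionization-fraction algebra, ideal activities).
oracle_ph_bisect <- function(dic = 0, sulfide = 0, sulfate = 0,
                             thiosulfate = 0, mg = 0, ca = 0, na = 0, cl = 0,
                             K1 = 4.45e-7, K2 = 4.69e-11, Kw = 1e-14,
                             Ka1 = 8.9e-8) {
  resid <- function(ph) {
    h <- 10^(-ph)
    oh <- Kw / h
    den <- h^2 + K1 * h + K1 * K2
    hco3 <- dic * K1 * h / den
    co3 <- dic * K1 * K2 / den
    hs <- sulfide * Ka1 / (h + Ka1)
    2 * mg + 2 * ca + na + h -
      (2 * sulfate + 2 * thiosulfate + cl + oh + hco3 + 2 * co3 + hs)
  }
  lo <- 0; hi <- 14
  if (resid(lo) < 0 || resid(hi) > 0) stop("oracle: root not in [0, 14]")
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Davies formula written out directly (closed-form oracle).
oracle_davies <- function(I, z, A = 0.5085, b = 0.3) {
  10^(-A * z^2 * (sqrt(I) / (1 + sqrt(I)) - b * I))
}

# Cheap single-phase validation configuration for calibration tests: the
# biomass trajectory is essentially mineral-independent (growth is not pH
# modulated), so one phase and a short horizon suffice.
fast_validation_scenario <- function(horizon = 240, thiosulfate = 0.02) {
  validation_scenario(thiosulfate = thiosulfate,
                      fractions = c(serpentine = 1),
                      horizon = horizon, dt = 12,
                      rtol = 1e-7, atol = 1e-11)
}

# Scaled-down stage scenarios to keep integration tests fast.
small_oxidation <- function(variant = "s2o3", max_time = 1200, ...) {
  oxidation_scenario(variant, substrate = 0.1, forsterite = 40,
                     radius = 25e-6, max_time = max_time, dt = 2, ...)
}

small_reduction <- function(variant = "h2s", max_time = 1200, ...) {
  reduction_scenario(variant, mg = 0.1, max_time = max_time, dt = 2, ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
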