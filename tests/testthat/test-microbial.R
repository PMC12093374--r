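pox <- oxidizer_params()
pred <- reducer_params()

test_that("oxidizer growth modifier has the dual-Monod structure", {
  # zero substrate: no growth, pure decay, no conversion
  r0 <- oxidizer_rates(100, 0, 8, pox, "s2o3")
  expect_equal(r0$gamma, 0)
  expect_equal(r0$dX, -pox$k_d * 100)
  expect_equal(r0$substrate_mol, 0)
  expect_equal(r0$o2_mol, 0)
  expect_equal(r0$proton_mol, 0)
  # both saturating: gamma -> 1
  rs <- oxidizer_rates(100, 1e6 * pox$K_S, 1e6 * pox$K_O, pox, "s2o3")
  expect_equal(rs$gamma, 1, tolerance = 1e-5)
  expect_equal(rs$dX, (pox$mu_max - pox$k_d) * 100, tolerance = 1e-4)
  # both at half saturation: product of Monod terms = 0.25 exactly
  rh <- oxidizer_rates(100, pox$K_S, pox$K_O, pox, "s2o3")
  expect_equal(rh$gamma, 0.25)
  # strictly increasing in each substrate, bounded by 1
  g <- vapply(c(1, 5, 20, 100, 1000),
              function(s) oxidizer_rates(1, s, 8, pox, "s2o3")$gamma, 0)
  expect_true(all(diff(g) > 0) && all(g < 1))
})

test_that("oxidizer stoichiometry is independent of kinetic parameters", {
  for (p in list(pox, oxidizer_params(list(mu_max = 0.3, yield = 0.01)))) {
    r <- oxidizer_rates(50, 500, 8, p, "s2o3")
    # per mol S2O3: 2 SO4, 2 H+, 2 O2
    expect_equal(r$sulfate_mol / r$substrate_mol, 2)
    expect_equal(r$proton_mol / r$substrate_mol, 2)
    expect_equal(r$o2_mol / r$substrate_mol, 2)
    rh <- oxidizer_rates(50, 5, 8, p, "h2s")
    expect_equal(rh$sulfate_mol / rh$substrate_mol, 1)
    expect_equal(rh$proton_mol / rh$substrate_mol, 2)
    expect_equal(rh$o2_mol / rh$substrate_mol, 2)
  }
})

test_that("infinite yield decouples biomass growth from substrate use", {
  p <- oxidizer_params(list(yield = 1e15))
  r <- oxidizer_rates(100, 500, 8, p, "s2o3")
  expect_gt(r$dX, 0)
  expect_lt(r$substrate_mol, 1e-12)
})

test_that("reducer kinetics follow the dual-Monod law and stoichiometry", {
  r0 <- reducer_rates(1, 0.5, 0, pred, "h2s")
  expect_equal(r0$r_S, 0)
  expect_equal(r0$dX, -pred$k_d * 1)
  rh <- reducer_rates(1, pred$K_S_sulfate, pred$K_H, pred, "h2s")
  expect_equal(rh$r_X, 0.25 * pred$mu_max_S)
  # H2S product: 4 H2 and 2 H+ per sulfate
  r <- reducer_rates(2, 0.3, 1e-4, pred, "h2s")
  expect_equal(r$h2_mol / r$r_S, 4)
  expect_equal(r$proton_mol / r$r_S, 2)
  expect_equal(r$product_mol / r$r_S, 1)
  # thiosulfate product: 2 H2, 1 H+, 0.5 S2O3 per sulfate
  r2 <- reducer_rates(2, 0.3, 1e-4, pred, "s2o3")
  expect_equal(r2$h2_mol / r2$r_S, 2)
  expect_equal(r2$proton_mol / r2$r_S, 1)
  expect_equal(r2$product_mol / r2$r_S, 0.5)
  expect_equal(r2$r_S, r2$r_X / pred$Y_S)
})

test_that("negative kinetic inputs are rejected", {
  expect_error(oxidizer_rates(-1, 1, 1, pox, "s2o3"), ">= 0")
  expect_error(reducer_rates(1, -1, 1, pred, "h2s"), ">= 0")
})

test_that("decay-only biomass follows the exponential closed form", {
  # with all substrates zero the ODE is dX/dt = -k_d X
  rhs <- function(t, y, p) {
    list(oxidizer_rates(y[[1]], 0, 0, pox, "s2o3")$dX)
  }
  out <- deSolve::lsoda(c(X = 100), seq(0, 100, 10), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(out[, "X"], 100 * exp(-pox$k_d * out[, "time"]),
               tolerance = 1e-7)
})

test_that("mu_max is recovered from noise-free biomass data within 1%", {
  scen <- fast_validation_scenario()
  simulator <- validation_biomass_simulator(scen)
  times <- seq(24, 240, by = 24)
  truth <- 0.012
  traj <- simulator(truth, times)
  fit <- calibrate_mu_max(data.frame(time = times, biomass = traj),
                          simulator = simulator, interval = c(0.004, 0.04),
                          ci = FALSE)
  expect_rel_equal(fit$mu_max, truth, 0.01)
})

test_that("noisy calibration agrees with a grid-search oracle", {
  scen <- fast_validation_scenario()
  simulator <- validation_biomass_simulator(scen)
  times <- seq(24, 240, by = 24)
  truth <- 0.0117
  traj <- simulator(truth, times)
  set.seed(202)
  obs <- traj * exp(0.05 * rnorm(length(times)))
  fit <- calibrate_mu_max(data.frame(time = times, biomass = obs),
                          simulator = simulator, interval = c(0.008, 0.016))
  # independent grid search at 1e-4 resolution on the same objective
  grid <- seq(0.008, 0.016, by = 1e-4)
  sse <- vapply(grid, function(mu) {
    sum((log(obs) - log(pmax(simulator(mu, times), 1e-300)))^2)
  }, 0)
  mu_grid <- grid[which.min(sse)]
  expect_lt(abs(fit$mu_max - mu_grid), 1e-4)
  expect_true(fit$ci[1] <= fit$mu_max && fit$mu_max <= fit$ci[2])
})

test_that("degenerate calibration data raise identifiability warnings", {
  sim <- function(mu, times) 10 * exp(mu * times)
  w1 <- capture_warnings(
    calibrate_mu_max(data.frame(time = c(0, 50), biomass = c(10, 20)),
                     simulator = sim, interval = c(1e-3, 0.1)))
  expect_true(any(grepl("non-identifiable", w1)))
  w2 <- capture_warnings(
    calibrate_mu_max(data.frame(time = seq(0, 100, 20),
                                biomass = rep(5, 6)),
                     simulator = sim, interval = c(1e-3, 0.1)))
  expect_true(any(grepl("flat", w2)))
})
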