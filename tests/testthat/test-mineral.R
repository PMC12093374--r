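db <- mineral_db()
fo <- db$forsterite
ec <- equilibrium_constants()

test_that("specific dissolution rate follows the modified Arrhenius law", {
  # order-zero phase: rate independent of pH, equal to A exp(-E/RT)
  p0 <- mineral_phase("test0", 100, 3e6, 5e4, 0, arrhenius_A = 1e6,
                      cations = c(mg = 1), protons = 2)
  expect_equal(specific_rate(p0, 1e-2), specific_rate(p0, 1e-9))
  expect_equal(specific_rate(p0, 1), 1e6 * exp(-5e4 / (8.314462618 * 298.15)))
  # power-law scaling: a_H x10 with n = 0.5 scales the rate by 10^0.5
  p5 <- mineral_phase("test5", 100, 3e6, 5e4, 0.5, arrhenius_A = 1e6,
                      cations = c(mg = 1), protons = 2)
  expect_rel_equal(specific_rate(p5, 1e-2) / specific_rate(p5, 1e-3),
                   10^0.5, 1e-12)
  # activation energies differing by R T ln 2 give exactly a factor 2
  pE <- mineral_phase("testE", 100, 3e6,
                      5e4 + 8.314462618 * 298.15 * log(2), 0,
                      arrhenius_A = 1e6, cations = c(mg = 1), protons = 2)
  expect_rel_equal(specific_rate(p0, 1) / specific_rate(pE, 1), 2, 1e-12)
  # monotone in acidity for n > 0
  rates <- specific_rate(fo, 10^seq(-8, -1, by = 1))
  expect_true(all(diff(rates) > 0))
})

test_that("particle count matches the hand-computed n = 3m/(4 pi rho R^3)", {
  pp <- particle_population(fo, radius = 50e-6, mass = 10)
  n_hand <- 3 * 10 / (4 * pi * fo$density * (50e-6)^3)
  expect_rel_equal(pp$count, n_hand, 1e-12)
  expect_rel_equal(population_mass(pp), 10, 1e-12)
})

test_that("exhausted particles produce zero rates", {
  pp <- particle_population(fo, radius = 50e-6, mass = 200)
  pr <- population_rates(pp, 1e-4, radius = 0)
  expect_equal(pr$area, 0)
  expect_equal(unname(pr$cation_rates["mg"]), 0)
  expect_equal(pr$dR, 0)
})

test_that("radius shrinks linearly at clamped acidity and mass is conserved", {
  pp <- particle_population(fo, radius = 50e-6, mass = 200)
  r_dis <- specific_rate(fo, a_h = 0.1)  # constant: pH clamped
  rhs <- function(t, y, p) {
    pr <- population_rates(pp, r_dis, radius = y[["rp"]])
    list(c(rp = pr$dR, mg = unname(pr$cation_rates["mg"])))
  }
  times <- seq(0, 40, by = 5)
  out <- deSolve::lsoda(c(rp = 50e-6, mg = 0), times, rhs, NULL,
                        rtol = 1e-10, atol = c(1e-16, 1e-14))
  # closed form: R(t) = R0 - (M/rho) r_dis t
  r_ref <- 50e-6 - fo$molar_mass / fo$density * r_dis * times
  expect_equal(out[, "rp"], r_ref, tolerance = 1e-6)
  expect_true(all(diff(out[, "rp"]) < 0))
  # mass ledger: dissolved Mg + remaining particle mass = initial charge
  for (i in seq_along(times)) {
    solid <- population_mass(pp, radius = out[i, "rp"])
    dissolved <- out[i, "mg"] / 2 * fo$molar_mass  # 2 Mg per formula unit
    expect_rel_equal(solid + dissolved, 200, 1e-9)
  }
})

test_that("dissolution charge accounting matches the cation release", {
  pp <- particle_population(fo, radius = 50e-6, mass = 200)
  pr <- population_rates(pp, 1e-4)
  expect_equal(pr$proton_rate, 2 * unname(pr$cation_rates["mg"]))
  expect_error(
    mineral_phase("bad", 100, 3e6, 5e4, 0.5, arrhenius_A = 1,
                  cations = c(mg = 1), protons = 3),
    "must equal")
})

test_that("single-phase tailings reduce to the forsterite path", {
  sp <- speciate(solution_state(na = 0.01, cl = 0.02), constants = ec)
  pp <- particle_population(fo, radius = 50e-6, mass = 100)
  tr <- tailings_rates(list(pp), sp, ec)
  r_dis <- specific_rate(fo, sp$activities[["h"]])
  pr <- population_rates(pp, r_dis)
  expect_equal(tr$mg_rate, unname(pr$cation_rates["mg"]))
  expect_equal(unname(tr$dR[1]), pr$dR)
  expect_equal(tr$ca_rate, 0)
})

test_that("halving the radius at fixed mass doubles the release rate", {
  sp <- speciate(solution_state(na = 0.01, cl = 0.02), constants = ec)
  r1 <- tailings_rates(list(particle_population(fo, 50e-6, mass = 100)),
                       sp, ec)$mg_rate
  r2 <- tailings_rates(list(particle_population(fo, 25e-6, mass = 100)),
                       sp, ec)$mg_rate
  expect_rel_equal(r2 / r1, 2, 1e-12)
})

test_that("carbonate phases stop dissolving at saturation", {
  cal <- db$calcite
  pp <- particle_population(cal, radius = 50e-6, mass = 10)
  # strongly supersaturated with respect to calcite
  sp_hi <- speciate(solution_state(ca = 0.05, dic = 0.05, na = 0.12),
                    constants = ec)
  expect_gt(saturation_index(sp_hi, ec, "calcite"), 1)
  tr_hi <- tailings_rates(list(pp), sp_hi, ec)
  expect_equal(tr_hi$ca_rate, 0)
  expect_equal(tr_hi$dic_rate, 0)
  # undersaturated: dissolves, releasing Ca and carbonate carbon
  sp_lo <- speciate(solution_state(ca = 1e-6, dic = 1e-6, cl = 0.01,
                                   na = 0.008), constants = ec)
  tr_lo <- tailings_rates(list(pp), sp_lo, ec)
  expect_gt(tr_lo$ca_rate, 0)
  expect_equal(tr_lo$dic_rate, tr_lo$ca_rate)
})

test_that("tailings composition must be complete and known", {
  expect_error(tailings_populations(fractions = c(forsterite = 0.5)),
               "sum to 1")
  expect_error(tailings_populations(fractions = c(unobtainium = 1)),
               "unknown phase")
})
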