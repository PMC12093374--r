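# Integration tests on scaled-down stage runs (0.1 mol/L sulfur charge,
# 40 g/L forsterite at 25 um) so the whole file stays fast; the invariants
# they check are scale-free.

ox_small <- step_oxidation(small_oxidation())
red_small <- suppressWarnings(step_reduction(small_reduction()))

test_that("scaled thiosulfate oxidation reaches its stoichiometric endpoint", {
  s <- attr(ox_small, "summary")
  expect_true(s$terminated_by_event)
  # 0.1 mol/L S2O3 -> 0.2 mol/L sulfate, 0.2 mol/L H+ -> 0.1 mol/L Mg2+
  expect_rel_equal(s$sulfate_peak, 0.2, 1e-3)
  expect_rel_equal(s$mg_released, 0.1, 5e-3)
  expect_gte(s$ph_end, 6.5)
  expect_lt(s$ph_min, 2)
  # thiosulfate S conserved into sulfate: 2*sub + so4 constant
  stot <- 2 * ox_small$sub + ox_small$so4
  expect_true(all(abs(stot - stot[1]) / stot[1] < 1e-6))
})

test_that("oxidation ledgers close: forsterite mass and charge", {
  scen <- attr(ox_small, "scenario")
  pop <- scen$population
  m0 <- population_mass(pop)
  # dissolved Mg + remaining particle inventory = initial charge
  for (i in seq(1, nrow(ox_small), length.out = 12)) {
    solid <- population_mass(pop, radius = ox_small$rp[i])
    dissolved <- ox_small$mg[i] / 2 * pop$phase$molar_mass
    expect_rel_equal(solid + dissolved, m0, 1e-6)
  }
  expect_true(all(diff(ox_small$rp) <= 1e-12))
  expect_true(all(ox_small$rp >= 0))
  expect_true(all(abs(ox_small$charge_residual) < 1e-10))
})

test_that("reduction controller, stoichiometric caps, and ledgers hold", {
  scen <- attr(red_small, "scenario")
  s <- attr(red_small, "summary")
  # pH never exceeds the setpoint plus the controller tolerance
  expect_lte(max(red_small$ph), scen$h2_control$setpoint +
               scen$h2_control$deadband + 0.01)
  # captured CO2 never exceeds the Mg supplied
  expect_true(all(red_small$prec <= scen$mg0 + 1e-9))
  # Mg ledger: dissolved + precipitated = influent
  expect_true(all(abs(red_small$mg + red_small$prec - scen$mg0) /
                    scen$mg0 < 1e-6))
  # carbon ledger: DIC + precipitate = cumulative CO2 absorbed
  i <- nrow(red_small)
  expect_rel_equal(red_small$dic[i] + red_small$prec[i],
                   red_small$co2_abs[i], 1e-6)
  # sulfur ledger: sulfate + aqueous sulfide + vented = influent sulfate
  expect_true(all(abs(red_small$so4 + red_small$red + red_small$vented -
                        scen$sulfate0) / scen$sulfate0 < 1e-6))
  # hydrogen ledger: dissolved + consumed = fed
  expect_rel_equal(red_small$clh[i] + red_small$h2_cons[i],
                   red_small$h2_fed[i], 1e-6)
  expect_true(all(abs(red_small$charge_residual) < 1e-10))
  # H2 mass efficiency approaches the stoichiometric 44.01 g CO2 per
  # 4 mol H2 (8.064 g)
  expect_rel_equal(s$co2_per_h2_g_g, 44.01 / (4 * 2.016), 0.05)
})

test_that("without microbes or substrate, dissolution alone raises pH", {
  # CO2-free aeration isolates the mineral contribution to the pH trajectory
  reg <- load_registry(overrides = list(gas = list(co2_ppm = 0)))
  scen <- oxidation_scenario("s2o3", substrate = 0, na = 0, X0 = 0,
                             forsterite = 40, radius = 25e-6,
                             max_time = 60, dt = 5, registry = reg)
  tr <- step_oxidation(scen)
  expect_true(all(diff(tr$ph) > -1e-9))
  expect_equal(tr$so4, rep(0, nrow(tr)))
})

test_that("zero sulfate influent gives no pH rise and no precipitation", {
  scen <- reduction_scenario("h2s", mg = 0.2, sulfate = 0, cl = 0.4,
                             max_time = 24, dt = 2)
  tr <- step_reduction(scen)
  expect_lt(max(tr$ph), 7.5)
  expect_lt(max(tr$prec), 1e-6)
  expect_equal(tr$h2_cons[nrow(tr)], 0, tolerance = 1e-12)
})

test_that("results are invariant to halved integrator tolerances", {
  a <- step_oxidation(small_oxidation(max_time = 150))
  b <- step_oxidation(small_oxidation(max_time = 150, rtol = 5e-9,
                                      atol = 5e-13))
  i <- nrow(a)
  expect_equal(nrow(b), i)
  for (v in c("X", "so4", "mg", "rp", "ph")) {
    expect_rel_equal(b[[v]][i], a[[v]][i], 1e-4)
  }
  # residual substrate is essentially zero by then; compare absolutely
  expect_lt(abs(b$sub[i] - a$sub[i]), 1e-8)
})

test_that("identical configurations give identical trajectories and events", {
  s1 <- step_oxidation(small_oxidation(max_time = 100))
  s2 <- step_oxidation(small_oxidation(max_time = 100))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(attr(s1, "summary"), attr(s2, "summary"))
})

test_that("validation run preserves the radius ordering of metal release", {
  scen <- validation_scenario(horizon = 300, dt = 20)
  v <- run_validation_scenario(scen, radii = c(10e-6, 50e-6, 200e-6))
  byr <- split(v, v$radius_m)
  stopifnot(length(byr) == 3)
  for (i in 2:15) {  # common output grid
    mgs <- vapply(byr, function(d) d$mg_mg_l[i], 0)
    expect_true(all(diff(mgs) <= 1e-9 + 1e-6 * abs(mgs[-3])))
  }
})

test_that("with no tailings the pH falls monotonically under oxidation", {
  scen <- validation_scenario(tailings_g = 0, horizon = 200, dt = 10)
  v <- run_validation_scenario(scen, radii = 50e-6)
  expect_true(all(diff(v$ph) < 1e-9))
  expect_lt(v$ph[nrow(v)], 4)
})

test_that("a scaled thiosulfate cycle is internally consistent", {
  cy <- suppressWarnings(
    run_cycle("s2o3", substrate = 0.1, forsterite = 40, radius = 25e-6,
              dt = 2))
  s <- cy$summary
  # CO2 per cycle tracks the Mg made available by the oxidation charge
  expect_rel_equal(s$co2_g_l, 44.01 * 0.1, 0.05)
  expect_rel_equal(s$sulfate_peak_mol_l, 0.2, 0.01)
  expect_rel_equal(s$mg_released_mol_l, 0.1, 0.01)
  # event table: windows are ordered and positive
  expect_true(all(cy$events$end_h >= cy$events$start_h))
  expect_equal(s$cycle_h, max(attr(cy$oxidation, "summary")$duration_h,
                              attr(cy$reduction, "summary")$duration_h))
})
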