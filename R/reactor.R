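# Reactor assembly and cycle scheduling.
#
# Each bioreactor is a coupled differential-algebraic system: slow processes
# (microbial growth and conversion, mineral dissolution, seeded
# precipitation, gas-liquid transfer) are ODEs in the total component
# concentrations, while the fast acid-base chemistry is eliminated
# algebraically by solving the charge-balance speciation inside the
# right-hand side (index-1 elimination). Proton bookkeeping is implicit:
# reactions change conservative totals (sulfate, thiosulfate, Mg2+, DIC,
# total sulfide) and the charge balance returns the pH, so the printed
# reaction stoichiometries are honoured exactly. Integration uses the stiff
# variable-order solver lsodar with terminal stage-end roots.

.M_O2_MG <- 32000   # mg/mol
.M_H2_G <- 2.016    # g/mol
.M_CO2_G <- 44.01
.M_MG_MG <- 24305   # mg/mol
.M_CA_MG <- 40078

#' Oxidation-bioreactor scenario
#'
#' Default operating conditions: 1 m3 liquid, 25 C, 1 atm, 100 rpm, 360 m3/h
#' air feed, 200 g/L forsterite at 50 um particle radius. The thiosulfate
#' variant starts with a 0.5 mol/L thiosulfate charge (with its monovalent
#' counter-cation background); the H2S variant starts in mineral-only medium
#' and receives H2S through the gas feed, by default 0.5 mol per litre of
#' liquid spread uniformly over 164 h (in a full cycle the feed profile is
#' replaced by the reduction reactor's actual generation profile).
#'
#' @param variant `"s2o3"` or `"h2s"`.
#' @param substrate Reduced-sulfur charge (mol per L of liquid): initial
#'   thiosulfate, or total H2S fed.
#' @param na Background monovalent cation (mol/L); defaults to the
#'   charge-balancing counter-ion of the thiosulfate charge, 0 for H2S.
#' @param cl Background monovalent anion (mol/L).
#' @param forsterite Forsterite loading (g/L).
#' @param radius Initial particle radius (m).
#' @param X0 Oxidizer inoculum (mg dry weight/L).
#' @param feed_duration H2S feed window (h; H2S variant only).
#' @param feed_profile Optional function `f(t)` giving the H2S feed in mol/h
#'   (overrides the uniform default; H2S variant only).
#' @param oxidizer [oxidizer_params()].
#' @param transfer [transfer_settings()].
#' @param kla Named k_L.a vector (1/h) for `o2`, `co2`, `h2s`; estimated
#'   from `transfer` when `NULL`.
#' @param constants [equilibrium_constants()].
#' @param registry Parameter registry.
#' @param max_time Simulation horizon (h).
#' @param dt Output interval (h).
#' @param rtol,atol Integrator tolerances.
#' @param substrate_tol Stage-end residual substrate threshold (mol/L).
#' @param ph_neutral Stage-end neutral-band pH threshold.
#' @return Object of class `reactor_scenario`.
#' @export
oxidation_scenario <- function(variant = c("s2o3", "h2s"), substrate = 0.5,
                               na = NULL, cl = 0, forsterite = 200,
                               radius = 50e-6,
                               X0 = 50, feed_duration = 164,
                               feed_profile = NULL,
                               oxidizer = NULL,
                               transfer = transfer_settings(),
                               kla = NULL,
                               constants = equilibrium_constants(),
                               registry = load_registry(),
                               max_time = 2000, dt = 1,
                               rtol = 1e-8, atol = 1e-12,
                               substrate_tol = 1e-6, ph_neutral = 6.5) {
  variant <- match.arg(variant)
  if (is.null(oxidizer)) {
    oxidizer <- oxidizer_params(substrate = variant, registry = registry)
  }
  if (is.null(na)) na <- if (variant == "s2o3") 2 * substrate else 0
  if (is.null(kla)) {
    kla <- c(o2 = estimate_kla(transfer, "o2", warn = FALSE),
             co2 = estimate_kla(transfer, "co2", warn = FALSE),
             h2s = estimate_kla(transfer, "h2s", warn = FALSE))
  }
  V_L <- transfer$liquid_volume * 1000  # L
  if (variant == "h2s" && is.null(feed_profile)) {
    total <- substrate * V_L
    rate <- total / feed_duration
    fd <- feed_duration
    feed_profile <- function(t) ifelse(t >= 0 & t < fd, rate, 0)
  }
  db <- mineral_db()
  scen <- list(
    type = "oxidation", variant = variant,
    substrate0 = if (variant == "s2o3") substrate else 0,
    feed_total = if (variant == "h2s") substrate else 0,
    na = na, cl = cl, X0 = X0,
    population = particle_population(db$forsterite, radius = radius,
                                     mass = forsterite),
    feed_profile = feed_profile,
    feed_end = if (variant == "h2s") feed_duration else -1e-6,
    oxidizer = oxidizer, transfer = transfer, kla = kla,
    constants = constants,
    gas = list(pressure = registry$gas$pressure,
               temperature = registry$gas$temperature,
               co2_ppm = registry$gas$co2_ppm, o2_frac = 0.2095),
    liquid_volume = V_L,
    max_time = max_time, dt = dt, rtol = rtol, atol = atol,
    substrate_tol = substrate_tol, ph_neutral = ph_neutral
  )
  class(scen) <- "reactor_scenario"
  scen
}

#' Reduction-bioreactor scenario
#'
#' Default operating conditions: 1 m3 liquid, 25 C, 1 atm, 100 rpm, 360 m3/h
#' air feed (CO2 source at atmospheric concentration), MgCO3 seeds with
#' 1 m2/L initial surface area, hydrogen supplied as a dissolved-phase feed
#' throttled so the pH stays at or below the setpoint (default 10). The H2S
#' variant starts from an MgSO4-type influent (0.5 mol/L each); the
#' thiosulfate variant from the completed oxidation batch (1 mol/L sulfate,
#' 0.5 mol/L Mg2+, 1 mol/L background cation).
#'
#' @param variant `"h2s"` or `"s2o3"` (the reduced product).
#' @param mg,sulfate,na,cl Influent composition (mol/L); variant defaults as
#'   above, `cl = 0`.
#' @param X0 Reducer inoculum (g/L).
#' @param reducer [reducer_params()].
#' @param seeds [seed_population()].
#' @param h2_fmax Maximum dissolved-H2 feed rate (mol/L/h).
#' @param ph_setpoint,ph_deadband H2-feed controller settings; feed is fully
#'   on `deadband` pH units below the setpoint and off at it.
#' @param omega_end Stage-end saturation-index threshold.
#' @param sulfate_tol Stage-end residual sulfate threshold (mol/L).
#' @inheritParams oxidation_scenario
#' @return Object of class `reactor_scenario`.
#' @export
reduction_scenario <- function(variant = c("h2s", "s2o3"), mg = 0.5,
                               sulfate = NULL, na = NULL, cl = 0, X0 = 0.1,
                               reducer = reducer_params(),
                               seeds = seed_population(),
                               transfer = transfer_settings(),
                               kla = NULL, h2_fmax = 0.05,
                               ph_setpoint = 10, ph_deadband = 0.05,
                               constants = equilibrium_constants(),
                               registry = load_registry(),
                               max_time = 2000, dt = 1,
                               rtol = 1e-8, atol = 1e-12,
                               sulfate_tol = 1e-6, omega_end = 1.05) {
  variant <- match.arg(variant)
  if (is.null(sulfate)) sulfate <- if (variant == "h2s") mg else 2 * mg
  if (is.null(na)) na <- max(0, 2 * sulfate - 2 * mg)
  if (is.null(kla)) {
    kla <- c(co2 = estimate_kla(transfer, "co2", warn = FALSE),
             h2s = estimate_kla(transfer, "h2s", warn = FALSE))
  }
  scen <- list(
    type = "reduction", variant = variant,
    mg0 = mg, sulfate0 = sulfate, na = na, cl = cl, X0 = X0,
    reducer = reducer, seeds = seeds, transfer = transfer, kla = kla,
    constants = constants,
    gas = list(pressure = registry$gas$pressure,
               temperature = registry$gas$temperature,
               co2_ppm = registry$gas$co2_ppm),
    h2_control = list(setpoint = ph_setpoint, deadband = ph_deadband,
                      fmax = h2_fmax,
                      c_sat = constants$henry[["h2"]] * registry$gas$pressure),
    liquid_volume = transfer$liquid_volume * 1000,
    max_time = max_time, dt = dt, rtol = rtol, atol = atol,
    sulfate_tol = sulfate_tol, omega_end = omega_end
  )
  class(scen) <- "reactor_scenario"
  scen
}

#' Tailings-dissolution validation scenario
#'
#' A 200 mL static culture, open to the atmosphere (surface aeration only,
#' no sparging), charged with mine tailings (default 10 g at 50 um radius)
#' and a thiosulfate growth medium. Emulates a flask experiment in which a
#' sulfur oxidizer acidifies the medium and dissolves the tailings,
#' releasing Ca2+ and Mg2+.
#'
#' @param radius Tailings particle radius (m).
#' @param tailings_g Tailings charge (g).
#' @param volume_l Culture volume (L).
#' @param thiosulfate Medium thiosulfate (mol/L) with its 2:1 monovalent
#'   counter-cation background.
#' @param X0 Inoculum (mg/L).
#' @param mu_max Oxidizer maximum specific growth rate (1/h); the default is
#'   the calibrated tailings-culture value.
#' @param fractions Tailings mass fractions (see [tailings_populations()]).
#' @param kla_surface Surface-aeration k_L.a for O2 (1/h); other species are
#'   scaled by diffusivity.
#' @param horizon Simulated duration (h).
#' @inheritParams oxidation_scenario
#' @return Object of class `reactor_scenario`.
#' @export
validation_scenario <- function(radius = 50e-6, tailings_g = 10,
                                volume_l = 0.2, thiosulfate = 0.04,
                                X0 = 5, mu_max = 0.0117,
                                fractions = NULL,
                                kla_surface = 1.0,
                                oxidizer = NULL,
                                constants = equilibrium_constants(),
                                registry = load_registry(),
                                horizon = 500, dt = 2,
                                rtol = 1e-8, atol = 1e-12) {
  if (is.null(oxidizer)) {
    oxidizer <- oxidizer_params(list(mu_max = mu_max), registry = registry)
  }
  dv <- unlist(registry$diffusivity)
  kla <- kla_surface * sqrt(dv / dv[["o2"]])
  args <- list(mass_g_per_l = tailings_g / volume_l, radius = radius)
  if (!is.null(fractions)) args$fractions <- fractions
  scen <- list(
    type = "validation", variant = "s2o3",
    substrate0 = thiosulfate, na = 2 * thiosulfate, X0 = X0,
    populations = do.call(tailings_populations, args),
    oxidizer = oxidizer, kla = kla, constants = constants,
    gas = list(pressure = registry$gas$pressure,
               temperature = registry$gas$temperature,
               co2_ppm = registry$gas$co2_ppm, o2_frac = 0.2095),
    liquid_volume = volume_l,
    max_time = horizon, dt = dt, rtol = rtol, atol = atol
  )
  class(scen) <- "reactor_scenario"
  scen
}

# per-state absolute tolerances: concentrations are tight, biomass and
# ledgers looser, radii very tight (metre scale)
.atol_for <- function(y, base) {
  a <- rep(base, length(y))
  names(a) <- names(y)
  a[grepl("^rp", names(y))] <- base * 1e-2
  a[names(y) == "X"] <- 1e-6
  a
}

# ---- oxidation reactor ------------------------------------------------------

.oxidation_rhs <- function(scen) {
  k <- scen$constants
  pars <- scen$oxidizer
  pop <- scen$population
  g <- scen$gas
  Q <- scen$transfer$gas_flow
  V_L <- scen$liquid_volume
  M_sub <- .M_SUBSTRATE[[if (scen$variant == "h2s") "h2s" else "s2o3"]]
  env <- new.env()
  env$ph <- 7
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    h2s_var <- scen$variant == "h2s"
    tot <- list(dic = y[["dic"]],
                sulfide = if (h2s_var) y[["sub"]] else 0,
                sulfate = y[["so4"]],
                thiosulfate = if (h2s_var) 0 else y[["sub"]],
                mg = y[["mg"]], ca = 0, na = scen$na, cl = scen$cl)
    sp <- .speciate_core(tot, k, start = env$ph)
    env$ph <- sp$ph
    ox <- oxidizer_rates(y[["X"]], mol_to_mg_per_l(y[["sub"]], M_sub),
                         mol_to_mg_per_l(y[["o2"]], 32),
                         params = pars, cycle_variant = scen$variant)
    r_dis <- specific_rate(pop$phase, sp$activities[["h"]], g$temperature)
    prt <- population_rates(pop, r_dis, radius = y[["rp"]])
    qs_o2 <- quasi_steady_gas(g$o2_frac, Q, scen$kla[["o2"]],
                              k$henry[["o2"]], y[["o2"]], V_L,
                              g$pressure, g$temperature)
    qs_co2 <- quasi_steady_gas(g$co2_ppm * 1e-6, Q, scen$kla[["co2"]],
                               k$henry[["co2"]], sp$co2, V_L,
                               g$pressure, g$temperature)
    feed <- 0; flux_h2s <- 0; vent_h2s <- 0
    if (h2s_var) {
      feed <- scen$feed_profile(t)                      # mol/h
      cg <- gas_molar_density(g$pressure, g$temperature)
      y_in <- if (Q > 0) feed / (Q * cg) else 0
      qs_h2s <- quasi_steady_gas(y_in, Q, scen$kla[["h2s"]],
                                 k$henry[["h2s"]], sp$h2s, V_L,
                                 g$pressure, g$temperature)
      flux_h2s <- qs_h2s$flux
      vent_h2s <- qs_h2s$vent
    }
    d <- c(
      X = ox$dX,
      sub = -ox$substrate_mol + flux_h2s,
      so4 = ox$sulfate_mol,
      mg = unname(prt$cation_rates["mg"] %|na|% 0),
      dic = qs_co2$flux,
      o2 = qs_o2$flux - ox$o2_mol,
      rp = prt$dR,
      fed = feed / V_L,
      vented = vent_h2s / V_L,
      co2_abs = qs_co2$flux
    )
    list(d, c(ph = sp$ph))
  }
  root <- function(t, y, p) {
    h2s_var <- scen$variant == "h2s"
    tot <- list(dic = max(y[["dic"]], 0),
                sulfide = if (h2s_var) max(y[["sub"]], 0) else 0,
                sulfate = max(y[["so4"]], 0),
                thiosulfate = if (h2s_var) 0 else max(y[["sub"]], 0),
                mg = max(y[["mg"]], 0), ca = 0, na = scen$na, cl = scen$cl)
    sp <- .speciate_core(tot, k, start = env$ph)
    min(sp$ph - scen$ph_neutral,
        (scen$substrate_tol - y[["sub"]]) * 1e3,
        t - scen$feed_end - 1e-9)
  }
  list(rhs = rhs, root = root)
}

#' Simulate the oxidation bioreactor
#'
#' Integrates oxidizer growth kinetics, gas-liquid transfer of the substrate
#' (H2S variant), O2 and CO2, and shrinking-particle forsterite dissolution,
#' with the charge-balance speciation solved at every step. The stage
#' terminates when the residual substrate falls below its threshold, the
#' feed window (if any) is over, and the pH has returned to the neutral
#' band; or at `max_time`.
#'
#' @param scen An [oxidation_scenario()].
#' @return A `reactor_trajectory`: data frame (one row per output time) with
#'   pH, totals (mol/L), biomass, particle radius, gas ledgers, and charge
#'   residual, plus attributes `summary` (list) and `scenario`.
#' @export
step_oxidation <- function(scen) {
  stopifnot(inherits(scen, "reactor_scenario"), scen$type == "oxidation")
  y0 <- c(X = scen$X0, sub = scen$substrate0, so4 = 0, mg = 0, dic = 0,
          o2 = scen$constants$henry[["o2"]] * scen$gas$pressure *
            scen$gas$o2_frac,
          rp = scen$population$radius, fed = 0, vented = 0, co2_abs = 0)
  fns <- .oxidation_rhs(scen)
  times <- seq(0, scen$max_time, by = scen$dt)
  out <- deSolve::lsodar(y0, times, fns$rhs, parms = NULL,
                         rtol = scen$rtol, atol = .atol_for(y0, scen$atol),
                         rootfunc = fns$root, maxsteps = 100000)
  .finish_oxidation(out, scen)
}

.finish_oxidation <- function(out, scen) {
  df <- as.data.frame(out)
  k <- scen$constants
  h2s_var <- scen$variant == "h2s"
  ns <- nrow(df)
  ph <- resid <- numeric(ns)
  start <- 7
  for (i in seq_len(ns)) {
    tot <- list(dic = max(df$dic[i], 0),
                sulfide = if (h2s_var) max(df$sub[i], 0) else 0,
                sulfate = max(df$so4[i], 0),
                thiosulfate = if (h2s_var) 0 else max(df$sub[i], 0),
                mg = max(df$mg[i], 0), ca = 0, na = scen$na, cl = scen$cl)
    sp <- .speciate_core(tot, k, start = start)
    ph[i] <- sp$ph; resid[i] <- sp$residual; start <- sp$ph
  }
  df$ph <- ph
  df$charge_residual <- resid
  pop <- scen$population
  mass0 <- population_mass(pop)
  dissolved_g_l <- mass0 - population_mass(pop, radius = df$rp[ns])
  sub_exh <- df$time[which(df$sub < scen$substrate_tol &
                             df$time > scen$feed_end)[1]]
  summary <- list(
    variant = scen$variant, duration_h = df$time[ns],
    substrate_exhausted_h = sub_exh,
    sulfate_peak = max(df$so4), sulfate_end = df$so4[ns],
    mg_released = df$mg[ns],
    forsterite_dissolved_g_l = dissolved_g_l,
    forsterite_dissolved_kg = dissolved_g_l * scen$liquid_volume / 1000,
    fed_total = df$fed[ns], vented_total = df$vented[ns],
    ph_end = df$ph[ns], ph_min = min(df$ph),
    terminated_by_event = df$time[ns] < scen$max_time
  )
  structure(df, class = c("reactor_trajectory", "data.frame"),
            summary = summary, scenario = scen)
}

# ---- reduction reactor ------------------------------------------------------

.reduction_rhs <- function(scen) {
  k <- scen$constants
  pars <- scen$reducer
  seeds <- scen$seeds
  g <- scen$gas
  ctl <- scen$h2_control
  Q <- scen$transfer$gas_flow
  V_L <- scen$liquid_volume
  env <- new.env()
  env$ph <- 7
  speciate_at <- function(y) {
    h2s_var <- scen$variant == "h2s"
    tot <- list(dic = max(y[["dic"]], 0),
                sulfide = if (h2s_var) max(y[["red"]], 0) else 0,
                sulfate = max(y[["so4"]], 0),
                thiosulfate = if (h2s_var) 0 else max(y[["red"]], 0),
                mg = max(y[["mg"]], 0), ca = 0, na = scen$na, cl = scen$cl)
    sp <- .speciate_core(tot, k, start = env$ph)
    env$ph <- sp$ph
    sp
  }
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    sp <- speciate_at(y)
    rr <- reducer_rates(y[["X"]], y[["so4"]], y[["clh"]], params = pars,
                        cycle_variant = scen$variant)
    u <- min(max((ctl$setpoint - sp$ph) / ctl$deadband, 0), 1) *
      max(0, 1 - y[["clh"]] / ctl$c_sat)
    feed <- ctl$fmax * u
    omega <- saturation_index(sp, k, "magnesite")
    r_prec <- precipitation_rate(omega, seeds$rate_constant, seeds$exponent)
    r_cap <- capture_rate(r_prec, y[["A"]])
    dA <- if (y[["A"]] > 0) area_growth(seeds, r_prec, area = y[["A"]]) else 0
    qs_co2 <- quasi_steady_gas(g$co2_ppm * 1e-6, Q, scen$kla[["co2"]],
                               k$henry[["co2"]], sp$co2, V_L,
                               g$pressure, g$temperature)
    flux_h2s <- 0; vent_h2s <- 0
    if (scen$variant == "h2s") {
      qs_h2s <- quasi_steady_gas(0, Q, scen$kla[["h2s"]],
                                 k$henry[["h2s"]], sp$h2s, V_L,
                                 g$pressure, g$temperature)
      flux_h2s <- qs_h2s$flux           # negative: stripping
      vent_h2s <- qs_h2s$vent
    }
    d <- c(
      X = rr$dX,
      so4 = -rr$r_S,
      mg = -r_cap,
      dic = qs_co2$flux - r_cap,
      red = rr$product_mol + flux_h2s,
      clh = feed - rr$h2_mol,
      A = dA,
      prec = r_cap,
      h2_fed = feed,
      h2_cons = rr$h2_mol,
      co2_abs = qs_co2$flux,
      vented = vent_h2s / V_L
    )
    list(d, c(ph = sp$ph, omega = omega, gen = vent_h2s))
  }
  root <- function(t, y, p) {
    sp <- speciate_at(pmax(y, 0))
    omega <- saturation_index(sp, k, "magnesite")
    min((scen$sulfate_tol - y[["so4"]]) * 1e3,
        scen$omega_end - omega)
  }
  list(rhs = rhs, root = root)
}

#' Simulate the reduction bioreactor
#'
#' Integrates sulfate-reducer kinetics (dissolved-H2 electron donor,
#' throttled by a pH-setpoint controller), air-CO2 absorption, seeded MgCO3
#' precipitation, and (H2S variant) stripping of the generated H2S into the
#' off-gas. The stage terminates when sulfate is exhausted and the magnesite
#' saturation index has fallen to the end threshold; or at `max_time`.
#'
#' @param scen A [reduction_scenario()].
#' @return A `reactor_trajectory` with attributes `summary` and `scenario`;
#'   columns include pH, the magnesite saturation index, totals, seed area,
#'   precipitated MgCO3, and the H2 and CO2 ledgers. The H2S-variant off-gas
#'   generation profile is in column `gen` (mol/h).
#' @export
step_reduction <- function(scen) {
  stopifnot(inherits(scen, "reactor_scenario"), scen$type == "reduction")
  y0 <- c(X = scen$X0, so4 = scen$sulfate0, mg = scen$mg0, dic = 0, red = 0,
          clh = 0, A = scen$seeds$area, prec = 0, h2_fed = 0, h2_cons = 0,
          co2_abs = 0, vented = 0)
  fns <- .reduction_rhs(scen)
  times <- seq(0, scen$max_time, by = scen$dt)
  out <- deSolve::lsodar(y0, times, fns$rhs, parms = NULL,
                         rtol = scen$rtol, atol = .atol_for(y0, scen$atol),
                         rootfunc = fns$root, maxsteps = 100000)
  .finish_reduction(out, scen)
}

.finish_reduction <- function(out, scen) {
  df <- as.data.frame(out)
  k <- scen$constants
  h2s_var <- scen$variant == "h2s"
  ns <- nrow(df)
  ph <- omega <- omega_br <- resid <- numeric(ns)
  start <- 7
  for (i in seq_len(ns)) {
    tot <- list(dic = max(df$dic[i], 0),
                sulfide = if (h2s_var) max(df$red[i], 0) else 0,
                sulfate = max(df$so4[i], 0),
                thiosulfate = if (h2s_var) 0 else max(df$red[i], 0),
                mg = max(df$mg[i], 0), ca = 0, na = scen$na, cl = scen$cl)
    sp <- .speciate_core(tot, k, start = start)
    ph[i] <- sp$ph
    resid[i] <- sp$residual
    omega[i] <- saturation_index(sp, k, "magnesite")
    omega_br[i] <- saturation_index(sp, k, "brucite")
    start <- sp$ph
  }
  df$ph <- ph; df$omega <- omega; df$charge_residual <- resid
  if (max(omega_br) > 1) {
    warning(sprintf(
      "brucite saturation monitor: Omega_Mg(OH)2 reached %.2f (> 1); the model does not precipitate brucite",
      max(omega_br)))
  }
  prec <- df$prec[ns]
  h2_g <- df$h2_cons[ns] * .M_H2_G
  summary <- list(
    variant = scen$variant, duration_h = df$time[ns],
    sulfate_reduced = scen$sulfate0 - df$so4[ns],
    sulfate_exhausted_h = df$time[which(df$so4 < scen$sulfate_tol)[1]],
    mgco3_mol_l = prec, co2_g_l = prec * .M_CO2_G,
    co2_kg = prec * .M_CO2_G * scen$liquid_volume / 1000,
    mg_remaining = df$mg[ns],
    h2_fed_mol_l = df$h2_fed[ns], h2_consumed_mol_l = df$h2_cons[ns],
    co2_per_h2_g_g = if (h2_g > 0) prec * .M_CO2_G / h2_g else NA_real_,
    product_generated = df$red[ns] + if (h2s_var) df$vented[ns] else 0,
    vented_s_mol_l = df$vented[ns],
    ph_max = max(df$ph), omega_brucite_max = max(omega_br),
    precipitation_start_h = df$time[which(df$prec > 1e-6)[1]],
    terminated_by_event = df$time[ns] < scen$max_time
  )
  structure(df, class = c("reactor_trajectory", "data.frame"),
            summary = summary, scenario = scen)
}

# ---- validation scenario ----------------------------------------------------

.validation_rhs <- function(scen) {
  k <- scen$constants
  pars <- scen$oxidizer
  pops <- scen$populations
  g <- scen$gas
  np <- length(pops)
  env <- new.env(); env$ph <- 7
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    tot <- list(dic = y[["dic"]], sulfide = 0, sulfate = y[["so4"]],
                thiosulfate = y[["sub"]], mg = y[["mg"]], ca = y[["ca"]],
                na = scen$na, cl = 0)
    sp <- .speciate_core(tot, k, start = env$ph)
    env$ph <- sp$ph
    ox <- oxidizer_rates(y[["X"]], mol_to_mg_per_l(y[["sub"]], 112.13),
                         mol_to_mg_per_l(y[["o2"]], 32), params = pars,
                         cycle_variant = "s2o3")
    radii <- y[paste0("rp", seq_len(np))]
    tr <- tailings_rates(pops, sp, k, g$temperature, radii = radii)
    qs_o2 <- quasi_steady_gas(g$o2_frac, 0, scen$kla[["o2"]],
                              k$henry[["o2"]], y[["o2"]], scen$liquid_volume,
                              g$pressure, g$temperature)
    qs_co2 <- quasi_steady_gas(g$co2_ppm * 1e-6, 0, scen$kla[["co2"]],
                               k$henry[["co2"]], sp$co2, scen$liquid_volume,
                               g$pressure, g$temperature)
    d <- c(
      X = ox$dX,
      sub = -ox$substrate_mol,
      so4 = ox$sulfate_mol,
      mg = tr$mg_rate,
      ca = tr$ca_rate,
      dic = qs_co2$flux + tr$dic_rate,
      o2 = qs_o2$flux - ox$o2_mol,
      stats::setNames(tr$dR, paste0("rp", seq_len(np)))
    )
    list(d, c(ph = sp$ph))
  }
  rhs
}

#' Run the tailings-dissolution validation scenario
#'
#' Simulates the static 200 mL tailings culture at one or more particle
#' radii (the known 50 um average plus 2.5 um and 1 mm extremes by default)
#' and returns the observables of the validation experiment: microbial
#' density, dissolved Ca2+ and Mg2+, and pH.
#'
#' @param scen A [validation_scenario()]; its `radius` is overridden by
#'   `radii`.
#' @param radii Particle radii (m) to simulate.
#' @return Data frame of class `validation_result` with columns `radius_m`,
#'   `time`, `biomass_g_l`, `ca_mg_l`, `mg_mg_l`, `ph`, `thiosulfate`,
#'   `sulfate`.
#' @export
run_validation_scenario <- function(scen = validation_scenario(),
                                    radii = c(2.5e-6, 50e-6, 1e-3)) {
  stopifnot(inherits(scen, "reactor_scenario"), scen$type == "validation")
  res <- lapply(radii, function(r) {
    s <- scen
    s$populations <- lapply(scen$populations, function(pp) {
      particle_population(pp$phase, radius = r,
                          mass = population_mass(pp))
    })
    np <- length(s$populations)
    y0 <- c(X = s$X0, sub = s$substrate0, so4 = 0, mg = 0, ca = 0, dic = 0,
            o2 = s$constants$henry[["o2"]] * s$gas$pressure * s$gas$o2_frac,
            stats::setNames(rep(r, np), paste0("rp", seq_len(np))))
    out <- deSolve::lsoda(y0, seq(0, s$max_time, by = s$dt),
                          .validation_rhs(s), parms = NULL,
                          rtol = s$rtol, atol = .atol_for(y0, s$atol),
                          maxsteps = 100000)
    df <- as.data.frame(out)
    data.frame(radius_m = r, time = df$time,
               biomass_g_l = df$X / 1000,
               ca_mg_l = df$ca * .M_CA_MG,
               mg_mg_l = df$mg * .M_MG_MG,
               ph = df$ph,
               thiosulfate = df$sub, sulfate = df$so4)
  })
  out <- do.call(rbind, res)
  class(out) <- c("validation_result", "data.frame")
  out
}

#' Biomass simulator for growth-rate calibration
#'
#' Returns a function `f(mu_max, times)` that reruns the validation scenario
#' with the given maximum specific growth rate and returns the biomass
#' trajectory (g/L) at `times`; the default simulator behind
#' [calibrate_mu_max()].
#'
#' @param scen A [validation_scenario()].
#' @return Function of `(mu_max, times)`.
#' @export
validation_biomass_simulator <- function(scen = validation_scenario()) {
  force(scen)
  function(mu_max, times) {
    s <- scen
    s$oxidizer$mu_max <- mu_max
    s$max_time <- max(times)
    gaps <- diff(sort(unique(times)))
    s$dt <- if (length(gaps)) {
      max(min(gaps) / 2, s$max_time / 500)
    } else {
      max(s$max_time / 50, 1)
    }
    tr <- run_validation_scenario(s, radii = scen$populations[[1]]$radius)
    stats::approx(tr$time, tr$biomass_g_l, xout = times, rule = 2)$y
  }
}

# ---- cycle orchestration ----------------------------------------------------

#' Run one complete two-reactor sulfur cycle
#'
#' Orchestrates the reduction and oxidation stages of one cycle. In the H2S
#' variant the reduction reactor's H2S off-gas generation profile is piped
#' (diluted into the oxidation air feed) as the oxidation substrate feed; in
#' the thiosulfate variant the completed reduction batch liquid (thiosulfate
#' plus background) is transferred to the oxidation reactor. The two batches
#' run on a common clock; the cycle time is the later stage end.
#'
#' @param variant `"h2s"` or `"s2o3"`.
#' @param substrate Reduced-sulfur charge scale c (mol/L): the reduction
#'   stage starts from `mg = c` and `sulfate = c` (H2S) or `sulfate = 2c`
#'   (thiosulfate).
#' @param forsterite Forsterite loading in the oxidation reactor (g/L).
#' @param radius Forsterite particle radius (m).
#' @param rpm Impeller speed (1/min) for both reactors.
#' @param transfer Base [transfer_settings()]; `rpm` overrides its speed.
#' @param max_time Per-stage integration horizon (h).
#' @param ... Passed to both scenario builders (e.g. `rtol`, `dt`).
#' @return Object of class `cycle_result`: list with `oxidation` and
#'   `reduction` trajectories, `events` (data frame of stage windows), and
#'   `summary` (cycle duration, CO2 captured g/L and kg, forsterite
#'   dissolved kg, sulfate converted mol/L, H2 efficiency).
#' @export
run_cycle <- function(variant = c("h2s", "s2o3"), substrate = 0.5,
                      forsterite = 200, radius = 50e-6, rpm = 100,
                      transfer = NULL, max_time = 2000, ...) {
  variant <- match.arg(variant)
  if (is.null(transfer)) transfer <- transfer_settings(rpm = rpm)
  red_scen <- reduction_scenario(variant, mg = substrate,
                                 sulfate = if (variant == "h2s") substrate
                                           else 2 * substrate,
                                 transfer = transfer, max_time = max_time,
                                 ...)
  red <- step_reduction(red_scen)
  red_sum <- attr(red, "summary")
  if (variant == "h2s") {
    gen <- stats::approxfun(red$time, red$gen, rule = 2, yleft = 0, yright = 0)
    ox_scen <- oxidation_scenario("h2s",
                                  substrate = red_sum$vented_s_mol_l,
                                  forsterite = forsterite, radius = radius,
                                  feed_profile = gen,
                                  feed_duration = red_sum$duration_h,
                                  transfer = transfer, max_time = max_time,
                                  ...)
  } else {
    ox_scen <- oxidation_scenario("s2o3",
                                  substrate = red_sum$product_generated,
                                  na = red_scen$na,
                                  forsterite = forsterite, radius = radius,
                                  transfer = transfer, max_time = max_time,
                                  ...)
  }
  ox <- step_oxidation(ox_scen)
  ox_sum <- attr(ox, "summary")
  sub_name <- if (variant == "h2s") "oxidation of H2S" else "oxidation of S2O3"
  gen_name <- if (variant == "h2s") "H2S gas generation" else "S2O3 generation"
  feed_start <- if (variant == "h2s") {
    t_on <- red$time[which(red$gen > 0)[1]]
    if (is.na(t_on)) 0 else t_on
  } else 0
  events <- data.frame(
    reactor = c("oxidation", "oxidation", "reduction", "reduction"),
    process = c(sub_name, "dissolution of forsterite", gen_name,
                "MgCO3 precipitation"),
    start_h = c(feed_start, feed_start, 0,
                red_sum$precipitation_start_h %|na|% NA_real_),
    end_h = c(ox_sum$substrate_exhausted_h %|na|% ox_sum$duration_h,
              ox_sum$duration_h,
              red_sum$sulfate_exhausted_h %|na|% red_sum$duration_h,
              red_sum$duration_h)
  )
  summary <- list(
    variant = variant,
    cycle_h = max(ox_sum$duration_h, red_sum$duration_h),
    co2_g_l = red_sum$co2_g_l, co2_kg = red_sum$co2_kg,
    forsterite_dissolved_kg = ox_sum$forsterite_dissolved_kg,
    sulfate_peak_mol_l = ox_sum$sulfate_peak,
    mg_released_mol_l = ox_sum$mg_released,
    co2_per_h2_g_g = red_sum$co2_per_h2_g_g
  )
  out <- list(oxidation = ox, reduction = red, events = events,
              summary = summary)
  class(out) <- "cycle_result"
  out
}

#' @export
print.cycle_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s cycle: %.0f h, CO2 captured %.2f g/L (%.1f kg), forsterite dissolved %.1f kg\n",
              toupper(s$variant), s$cycle_h, s$co2_g_l, s$co2_kg,
              s$forsterite_dissolved_kg))
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' Parameter sweep over full cycles
#'
#' Repeats [run_cycle()] over a grid of one operating parameter and tabulates
#' the cycle time and the CO2 captured per cycle.
#'
#' @param param One of `"radius"` (forsterite particle radius, m), `"rpm"`
#'   (impeller speed), `"substrate"` (reduced-sulfur charge, mol/L).
#' @param values Numeric vector of parameter values.
#' @param variant Cycle variant.
#' @param ... Passed to [run_cycle()] (fixed settings for the sweep).
#' @return Data frame with `param`, `value`, `cycle_h`, `co2_g_l`,
#'   `forsterite_kg`.
#' @export
sweep_parameter <- function(param = c("radius", "rpm", "substrate"), values,
                            variant = "s2o3", ...) {
  param <- match.arg(param)
  rows <- lapply(values, function(v) {
    args <- list(variant = variant, ...)
    args[[param]] <- v
    cy <- do.call(run_cycle, args)
    data.frame(param = param, value = v,
               cycle_h = cy$summary$cycle_h,
               co2_g_l = cy$summary$co2_g_l,
               forsterite_kg = cy$summary$forsterite_dissolved_kg)
  })
  do.call(rbind, rows)
}

#' @export
print.reactor_trajectory <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("reactor trajectory (%s, %s): %d points over %.0f h\n",
              attr(x, "scenario")$type, s$variant, nrow(x), s$duration_h))
  utils::str(s)
  invisible(x)
}
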