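# Shrinking-particle mineral dissolution.
#
# Monodisperse spherical particles dissolve at a surface-specific rate
# r_dis = A * exp(-E/(R T)) * a_H+^n (proton-promoted, far from equilibrium).
# The particle count is constant; the radius shrinks as dR/dt = -r_dis M/rho.
# Carbonate phases additionally carry an equilibrium cap: their rate is
# scaled by max(0, 1 - Omega) so dissolution stops at saturation.

.GAS_CONSTANT <- 8.314462618  # J/(K mol)

#' Mineral phase definition
#'
#' Rate-law and stoichiometry parameters for one mineral. The Arrhenius
#' factor can be given directly (`arrhenius_A`, mol m-2 h-1) or via
#' `log_k25`, the log10 dissolution rate at 25 C and unit H+ activity in
#' mol m-2 s-1 (the form rate compilations tabulate), from which
#' `A = 3600 * 10^log_k25 / exp(-E/(R*298.15))`.
#'
#' @param name Phase name.
#' @param molar_mass Molar mass (g/mol).
#' @param density Density (g/m3).
#' @param activation_energy Activation energy E (J/mol).
#' @param order Reaction order n with respect to H+ activity (>= 0).
#' @param arrhenius_A Arrhenius factor (mol m-2 h-1); alternative to
#'   `log_k25`.
#' @param log_k25 log10 rate at 25 C, a_H+ = 1, in mol m-2 s-1.
#' @param cations Named numeric: moles of divalent cation (`mg`, `ca`)
#'   released per formula unit.
#' @param protons Moles of H+ consumed per formula unit; must equal the
#'   charge released by the cations.
#' @param dic Moles of carbonate carbon released per formula unit (carbonate
#'   phases).
#' @param carbonate `NULL`, or the Ksp name (`"calcite"`, `"dolomite"`) used
#'   for the equilibrium cap.
#' @return Object of class `mineral_phase`.
#' @export
#' @examples
#' fo <- mineral_phase("forsterite", 140.69, 3.27e6, 67200, 0.47,
#'                     log_k25 = -6.85, cations = c(mg = 2), protons = 4)
mineral_phase <- function(name, molar_mass, density, activation_energy, order,
                          arrhenius_A = NULL, log_k25 = NULL,
                          cations = c(), protons = 0, dic = 0,
                          carbonate = NULL) {
  if (is.null(arrhenius_A)) {
    if (is.null(log_k25)) stop("give arrhenius_A or log_k25")
    arrhenius_A <- 3600 * 10^log_k25 /
      exp(-activation_energy / (.GAS_CONSTANT * 298.15))
  }
  cations <- unlist(cations)
  if (length(cations) && !all(names(cations) %in% c("mg", "ca"))) {
    stop("cations must be named 'mg' and/or 'ca'")
  }
  charge <- if (length(cations)) sum(2 * cations) else 0
  if (abs(charge - protons) > 1e-9) {
    stop(sprintf("phase %s: proton consumption (%g) must equal released cation charge (%g)",
                 name, protons, charge))
  }
  stopifnot(molar_mass > 0, density > 0, arrhenius_A > 0, order >= 0)
  out <- list(name = name, molar_mass = molar_mass, density = density,
              arrhenius_A = arrhenius_A, activation_energy = activation_energy,
              order = order, cations = cations, protons = protons, dic = dic,
              carbonate = carbonate)
  class(out) <- "mineral_phase"
  out
}

#' Load the bundled mineral database
#'
#' @param file YAML database path; defaults to the bundled file.
#' @return Named list of [mineral_phase()] objects.
#' @export
#' @examples
#' db <- mineral_db()
#' names(db)
mineral_db <- function(file = registry_file("minerals.yaml")) {
  raw <- yaml::read_yaml(file)
  out <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    mineral_phase(nm, e$molar_mass, e$density, e$activation_energy, e$order,
                  log_k25 = e$log_k25,
                  cations = e$cations %||% c(),
                  protons = e$protons %||% 0,
                  dic = e$dic %||% 0,
                  carbonate = e$carbonate)
  })
  names(out) <- names(raw)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monodisperse particle population
#'
#' The particle count per litre is fixed; particles shrink but never split.
#' Either the count or the initial mass loading must be given; from a mass
#' loading `n = m / ((4/3) pi R^3 rho)`.
#'
#' @param phase A [mineral_phase()].
#' @param radius Particle radius (m).
#' @param count Particles per litre of liquid.
#' @param mass Initial mass loading (g per litre of liquid).
#' @return Object of class `particle_population`: `phase`, `radius`, `count`.
#' @export
#' @examples
#' db <- mineral_db()
#' pp <- particle_population(db$forsterite, radius = 50e-6, mass = 200)
particle_population <- function(phase, radius, count = NULL, mass = NULL) {
  stopifnot(inherits(phase, "mineral_phase"), radius >= 0)
  if (is.null(count)) {
    if (is.null(mass)) stop("give count or mass")
    count <- mass / ((4 / 3) * pi * radius^3 * phase$density)
  }
  stopifnot(count >= 0)
  out <- list(phase = phase, radius = radius, count = count)
  class(out) <- "particle_population"
  out
}

#' Remaining particle mass of a population
#'
#' @param pop A [particle_population()].
#' @param radius Current radius (m); defaults to the population's radius.
#' @return Mass in g per litre of liquid.
#' @export
population_mass <- function(pop, radius = pop$radius) {
  (4 / 3) * pi * pmax(radius, 0)^3 * pop$count * pop$phase$density
}

#' Surface-specific dissolution rate
#'
#' `r_dis = A * exp(-E/(R T)) * a_H+^n`, strictly increasing in the H+
#' activity for `n > 0`.
#'
#' @param phase A [mineral_phase()].
#' @param a_h H+ activity (dimensionless, > 0).
#' @param temperature Temperature (K); the model is isothermal at 298.15 K.
#' @return Rate in mol m-2 h-1.
#' @export
#' @examples
#' db <- mineral_db()
#' specific_rate(db$forsterite, a_h = 1e-3)
specific_rate <- function(phase, a_h, temperature = 298.15) {
  stopifnot(inherits(phase, "mineral_phase"))
  if (any(a_h <= 0)) stop("a_h must be > 0")
  phase$arrhenius_A *
    exp(-phase$activation_energy / (.GAS_CONSTANT * temperature)) *
    a_h^phase$order
}

#' Dissolution rates of a particle population
#'
#' Converts a surface-specific rate into bulk liquid-phase rates using the
#' population surface area `4 pi R^2 n`. All rates are zero once the radius
#' reaches zero.
#'
#' @param pop A [particle_population()].
#' @param r_dis Surface-specific rate (mol m-2 h-1), e.g. from
#'   [specific_rate()].
#' @param radius Current radius (m); defaults to the population's.
#' @param taper Radius (m) below which all rates are ramped linearly to zero,
#'   so particle exhaustion is a smooth event for the integrator (default
#'   10 nm, far below any particle size of interest).
#' @return List: `area` (m2/L), `cation_rates` (named mol/L/h, release),
#'   `proton_rate` (mol/L/h, consumption >= 0), `dic_rate` (mol/L/h,
#'   release), `dR` (m/h, <= 0), `formula_rate` (mol formula units /L/h).
#' @export
population_rates <- function(pop, r_dis, radius = pop$radius, taper = 1e-8) {
  stopifnot(inherits(pop, "particle_population"))
  ph <- pop$phase
  if (radius <= 0) {
    z <- if (length(ph$cations)) {
      stats::setNames(numeric(length(ph$cations)), names(ph$cations))
    } else numeric(0)
    return(list(area = 0, cation_rates = z, proton_rate = 0, dic_rate = 0,
                dR = 0, formula_rate = 0))
  }
  r_dis <- r_dis * min(1, radius / taper)
  area <- 4 * pi * radius^2 * pop$count
  fr <- r_dis * area
  cat_rates <- if (length(ph$cations)) ph$cations * fr else numeric(0)
  list(area = area,
       cation_rates = cat_rates,
       proton_rate = ph$protons * fr,
       dic_rate = ph$dic * fr,
       dR = -r_dis * ph$molar_mass / ph$density,
       formula_rate = fr)
}

#' Dissolution rates of a multi-mineral tailings charge
#'
#' Applies [specific_rate()] and [population_rates()] to each phase
#' independently (each particle holds a single mineral) and aggregates the
#' Mg2+, Ca2+, proton and carbonate-carbon fluxes. Carbonate phases are
#' capped at saturation: their rate carries a factor `max(0, 1 - Omega)`.
#'
#' @param pops List of [particle_population()] objects.
#' @param spec A [speciate()] result for the current solution.
#' @param constants An [equilibrium_constants()] object.
#' @param temperature Temperature (K).
#' @param radii Optional numeric vector of current radii (m), same order as
#'   `pops`; defaults to each population's stored radius.
#' @return List: `per_phase` (named list of [population_rates()] outputs,
#'   plus `r_dis`), `mg_rate`, `ca_rate`, `proton_rate`, `dic_rate`
#'   (mol/L/h), `dR` (named m/h vector).
#' @export
tailings_rates <- function(pops, spec, constants = equilibrium_constants(),
                           temperature = 298.15, radii = NULL) {
  stopifnot(inherits(spec, "speciation_result"))
  if (is.null(radii)) radii <- vapply(pops, function(p) p$radius, 0)
  a_h <- spec$activities[["h"]]
  per <- vector("list", length(pops))
  names(per) <- vapply(pops, function(p) p$phase$name, "")
  mg <- ca <- pr <- dc <- 0
  dR <- stats::setNames(numeric(length(pops)), names(per))
  for (i in seq_along(pops)) {
    p <- pops[[i]]
    r <- specific_rate(p$phase, a_h, temperature)
    if (!is.null(p$phase$carbonate)) {
      om <- saturation_index(spec, constants, p$phase$carbonate)
      r <- r * max(0, 1 - om)
    }
    pr_i <- population_rates(p, r, radius = radii[i])
    pr_i$r_dis <- r
    per[[i]] <- pr_i
    mg <- mg + (pr_i$cation_rates["mg"] %|na|% 0)
    ca <- ca + (pr_i$cation_rates["ca"] %|na|% 0)
    pr <- pr + pr_i$proton_rate
    dc <- dc + pr_i$dic_rate
    dR[i] <- pr_i$dR
  }
  list(per_phase = per, mg_rate = unname(mg), ca_rate = unname(ca),
       proton_rate = pr, dic_rate = dc, dR = dR)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Build the tailings particle populations of the validation scenario
#'
#' Splits a total mass loading across mineral phases by mass fraction, all
#' at a common initial radius. The shipped composition is a documented
#' placeholder for a silicate-rich mine tailing (plagioclase, pyroxenes,
#' serpentine, talc, quartz, calcite, dolomite).
#'
#' @param mass_g_per_l Total tailings loading (g per litre of liquid).
#' @param radius Common initial particle radius (m).
#' @param fractions Named mass fractions (must sum to 1); names must exist in
#'   the mineral database.
#' @param db Mineral database from [mineral_db()].
#' @return List of [particle_population()] objects.
#' @export
tailings_populations <- function(mass_g_per_l = 50, radius = 50e-6,
                                 fractions = c(plagioclase = 0.18,
                                               clinopyroxene = 0.14,
                                               orthopyroxene = 0.10,
                                               serpentine = 0.22,
                                               talc = 0.06,
                                               quartz = 0.12,
                                               calcite = 0.08,
                                               dolomite = 0.10),
                                 db = mineral_db()) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("mass fractions must sum to 1")
  missing <- setdiff(names(fractions), names(db))
  if (length(missing)) stop("unknown phase name(s): ", paste(missing, collapse = ", "))
  lapply(names(fractions), function(nm) {
    particle_population(db[[nm]], radius = radius,
                        mass = mass_g_per_l * fractions[[nm]])
  })
}
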