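# Seeded MgCO3 crystal growth.
#
# Growth-only model: a fixed count of spherical seeds grows at a
# saturation-driven surface rate r_prec = k (Omega - 1)^p for Omega > 1
# (no nucleation, no seed dissolution below saturation). CO2 capture rate is
# r_cap = r_prec * A; the total seed surface area evolves with the per-seed
# radius, dA/dt = 8 pi n_s r dr/dt with dr/dt = r_prec M / rho.

#' MgCO3 seed crystal population
#'
#' @param area Initial total seed surface area (m2 per L).
#' @param radius Initial per-seed radius (m); with `area` it sets the seed
#'   count `n_s = A / (4 pi r^2)`.
#' @param count Seed count per litre (alternative to `radius`).
#' @param molar_mass,density MgCO3 molar mass (g/mol) and density (g/m3).
#' @param rate_constant Specific growth-rate constant k (mol m-2 h-1).
#' @param exponent Affinity-law exponent p (default 1).
#' @param registry Registry list supplying the defaults.
#' @return Object of class `seed_population`: `area`, `count`, `molar_mass`,
#'   `density`, `rate_constant`, `exponent`.
#' @export
#' @examples
#' sd <- seed_population()
#' sd$count
seed_population <- function(area = NULL, radius = NULL, count = NULL,
                            molar_mass = NULL, density = NULL,
                            rate_constant = NULL, exponent = NULL,
                            registry = load_registry()) {
  s <- registry$seeds
  area <- area %||% s$area
  radius <- radius %||% s$radius
  molar_mass <- molar_mass %||% s$molar_mass
  density <- density %||% s$density
  rate_constant <- rate_constant %||% s$rate_constant
  exponent <- exponent %||% s$exponent
  if (area <= 0) stop("seed area must be > 0")
  if (is.null(count)) count <- area / (4 * pi * radius^2)
  stopifnot(count > 0, molar_mass > 0, density > 0, rate_constant >= 0,
            exponent > 0)
  out <- list(area = area, count = count, molar_mass = molar_mass,
              density = density, rate_constant = rate_constant,
              exponent = exponent)
  class(out) <- "seed_population"
  out
}

#' Saturation-driven precipitation rate
#'
#' `r_prec = k (Omega - 1)^p` for `Omega > 1`, else 0 (seeds never dissolve
#' in this model).
#'
#' @param omega Saturation index (>= 0).
#' @param k Rate constant (mol m-2 h-1).
#' @param p Affinity-law exponent (default 1).
#' @return Rate in mol m-2 h-1.
#' @export
#' @examples
#' precipitation_rate(3, k = 1e-3)  # 2e-3
precipitation_rate <- function(omega, k, p = 1) {
  if (any(omega < 0)) stop("omega must be >= 0")
  k * pmax(omega - 1, 0)^p
}

#' CO2 capture rate from seeded growth
#'
#' `r_cap = r_prec * A`. Each mole of MgCO3 laid down consumes one mole of
#' dissolved inorganic carbon and one mole of Mg2+.
#'
#' @param r_prec Precipitation rate (mol m-2 h-1).
#' @param area Total seed surface area (m2/L).
#' @return Capture rate in mol L-1 h-1.
#' @export
capture_rate <- function(r_prec, area) {
  if (any(area < 0)) stop("area must be >= 0")
  r_prec * area
}

#' Seed surface-area growth rate
#'
#' Spherical-seed geometry: per-seed radius `r = sqrt(A / (4 pi n_s))`,
#' radial growth `dr/dt = r_prec M / rho`, hence
#' `dA/dt = 8 pi n_s r dr/dt`.
#'
#' @param seeds A [seed_population()].
#' @param r_prec Precipitation rate (mol m-2 h-1).
#' @param area Current total surface area (m2/L); defaults to the seeds'.
#' @return Area growth rate `r_A` in m2 L-1 h-1 (>= 0 for `r_prec >= 0`).
#' @export
area_growth <- function(seeds, r_prec, area = seeds$area) {
  stopifnot(inherits(seeds, "seed_population"))
  if (area <= 0) stop("seed area must be > 0")
  r <- sqrt(area / (4 * pi * seeds$count))
  drdt <- r_prec * seeds$molar_mass / seeds$density
  8 * pi * seeds$count * r * drdt
}

#' Grams of CO2 fixed per mole of MgCO3
#'
#' MgCO3 <-> CO2 accounting used for all "g CO2" outputs: each mole of
#' precipitate stores one mole of CO2 (44.01 g); equivalently, precipitated
#' MgCO3 mass times 44.01/84.31.
#'
#' @param mol_mgco3 Moles of MgCO3.
#' @return Grams of CO2.
#' @export
co2_mass_from_mgco3 <- function(mol_mgco3) 44.01 * mol_mgco3
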