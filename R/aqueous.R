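# Equilibrium speciation of the CO2-H2O-H2S-sulfate-Mg system.
#
# All homogeneous acid-base reactions are treated as instantaneous equilibria;
# pH is the root of the charge-balance equation, solved at fixed total
# (analytical) component concentrations. Activity corrections use the Davies
# equation; sulfate and thiosulfate are fully dissociated spectator anions
# that enter only the charge balance and the ionic strength.

#' Equilibrium constant set
#'
#' Assembles the equilibrium constants, Henry constants and activity-model
#' settings used by [speciate()] and [saturation_index()]. Values come from
#' the bundled parameter registry and can be overridden.
#'
#' @param overrides Named list of replacements, e.g. `list(Kw = 1e-14)`.
#'   Nested lists (`Ksp`, `henry`) are merged element-wise.
#' @param registry A registry list from [load_registry()].
#' @return An object of class `equilibrium_constants`: list with elements
#'   `K1`, `K2`, `Kw`, `Ka1_h2s`, `Ka2_h2s`, `Ksp` (named vector), `henry`
#'   (named vector), `davies_A`, `davies_b`, `I_cap`, `temperature`.
#' @export
#' @examples
#' ec <- equilibrium_constants()
#' ec$K1 > ec$K2
equilibrium_constants <- function(overrides = NULL, registry = load_registry()) {
  eq <- registry$equilibria
  act <- registry$activity
  k <- list(
    K1 = eq$K1_carbonate, K2 = eq$K2_carbonate, Kw = eq$Kw,
    Ka1_h2s = eq$Ka1_H2S, Ka2_h2s = eq$Ka2_H2S,
    Ksp = unlist(eq$Ksp),
    henry = unlist(registry$henry),
    davies_A = act$davies_A, davies_b = act$davies_b,
    I_cap = act$ionic_strength_cap,
    temperature = registry$gas$temperature
  )
  if (!is.null(overrides)) k <- modify_list_deep(k, overrides)
  stopifnot(
    all(unlist(k[c("K1", "K2", "Kw", "Ka1_h2s", "Ka2_h2s")]) > 0),
    all(k$Ksp > 0), all(k$henry > 0),
    k$K1 > k$K2, k$Ka1_h2s > k$Ka2_h2s
  )
  class(k) <- "equilibrium_constants"
  k
}

#' Liquid-phase solution state
#'
#' Total (analytical) concentrations of the dissolved components, in mol/L.
#' `dic` is total dissolved inorganic carbon, `sulfide` is total S(-II)
#' (H2S(aq) + HS-), `na` and `cl` are conservative background charge carriers
#' (use `na` for any monovalent background cation, `cl` for any monovalent
#' background anion). Dissolved O2 and H2 are uncharged and do not enter the
#' speciation; they are carried for the kinetic modules.
#'
#' @param dic,sulfide,sulfate,thiosulfate,mg,ca,na,cl Totals in mol/L.
#' @param o2,h2 Dissolved gas concentrations in mol/L.
#' @param temperature Temperature in K.
#' @param volume Liquid volume in L.
#' @return An object of class `solution_state` (named list).
#' @export
#' @examples
#' st <- solution_state(dic = 1e-3, na = 1e-3)
solution_state <- function(dic = 0, sulfide = 0, sulfate = 0, thiosulfate = 0,
                           mg = 0, ca = 0, na = 0, cl = 0, o2 = 0, h2 = 0,
                           temperature = 298.15, volume = 1) {
  st <- list(dic = dic, sulfide = sulfide, sulfate = sulfate,
             thiosulfate = thiosulfate, mg = mg, ca = ca, na = na, cl = cl,
             o2 = o2, h2 = h2, temperature = temperature, volume = volume)
  tot <- unlist(st[1:10])
  if (any(!is.finite(tot))) stop("solution totals must be finite")
  if (any(tot < 0)) stop("solution totals must be >= 0")
  if (volume <= 0) stop("volume must be > 0")
  class(st) <- "solution_state"
  st
}

#' Davies activity coefficients
#'
#' Single-ion activity coefficients from the Davies equation,
#' `log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - b I)`. Neutral species
#' (z = 0) get a coefficient of 1. The model is valid only up to moderate
#' ionic strength; above `I_cap` the ionic strength is clamped and a warning
#' is issued (once per call).
#'
#' @param ionic_strength Ionic strength in mol/L (scalar, >= 0).
#' @param charges Integer vector of species charges (sign is irrelevant).
#' @param constants An [equilibrium_constants()] object.
#' @param warn Emit a warning when the ionic strength is clamped.
#' @return Numeric vector of activity coefficients, same length as `charges`.
#' @export
#' @examples
#' activity_coefficients(0.1, c(0, 1, 2))
activity_coefficients <- function(ionic_strength, charges,
                                  constants = equilibrium_constants(),
                                  warn = TRUE) {
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  I <- ionic_strength
  if (I > constants$I_cap) {
    if (warn) {
      warning(sprintf(
        "ionic strength %.3g mol/L above Davies validity cap %.2g; clamped",
        I, constants$I_cap))
    }
    I <- constants$I_cap
  }
  sqI <- sqrt(I)
  lg <- -constants$davies_A * charges^2 * (sqI / (1 + sqI) - constants$davies_b * I)
  10^lg
}

# Species concentrations and charge-balance residual at a given H+ activity.
# g1, g2: activity coefficients of mono- and divalent ions; neutral = 1.
# Returns a list of concentrations plus residual (mol/L, cations - anions).
.species_at <- function(ha, tot, k, g1, g2, include_s2 = FALSE) {
  h <- ha / g1
  oh <- k$Kw / ha / g1
  D1 <- k$K1 / (ha * g1)
  D2 <- k$K1 * k$K2 / (ha^2 * g2)
  cden <- 1 + D1 + D2
  co2 <- tot[["dic"]] / cden
  hco3 <- co2 * D1
  co3 <- co2 * D2
  S1 <- k$Ka1_h2s / (ha * g1)
  S2 <- if (include_s2) k$Ka1_h2s * k$Ka2_h2s / (ha^2 * g2) else 0
  sden <- 1 + S1 + S2
  h2s <- tot[["sulfide"]] / sden
  hs <- h2s * S1
  s2 <- h2s * S2
  resid <- 2 * tot[["mg"]] + 2 * tot[["ca"]] + tot[["na"]] + h -
    (2 * tot[["sulfate"]] + 2 * tot[["thiosulfate"]] + tot[["cl"]] +
       oh + hco3 + 2 * co3 + hs + 2 * s2)
  list(h = h, oh = oh, co2 = co2, hco3 = hco3, co3 = co3,
       h2s = h2s, hs = hs, s2 = s2, resid = resid)
}

# Solve the charge balance for pH at fixed activity coefficients.
# Residual is strictly decreasing in pH, so the bracket is guaranteed.
.solve_ph <- function(tot, k, g1, g2, include_s2, start = NULL,
                      lower = -2, upper = 16, resid_tol = 1e-11) {
  f <- function(ph) .species_at(10^(-ph), tot, k, g1, g2, include_s2)$resid
  lo <- lower; hi <- upper
  if (!is.null(start) && is.finite(start)) {
    a <- max(lower, start - 0.5); b <- min(upper, start + 0.5)
    if (f(a) > 0 && f(b) < 0) { lo <- a; hi <- b }
  }
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0 || fhi > 0) {
    stop(sprintf(paste0(
      "charge-balance root not bracketed in pH [%g, %g]: ",
      "residual(%g) = %.3g, residual(%g) = %.3g"), lo, hi, lo, flo, hi, fhi))
  }
  ph <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  # Newton polish to machine level: the residual must sit far below the
  # integrator's Jacobian perturbations or the right-hand side looks noisy
  r <- f(ph)
  for (i in 1:40) {
    if (abs(r) < 1e-16) break
    dp <- 1e-7
    slope <- (f(ph + dp) - r) / dp
    if (!is.finite(slope) || slope == 0) break
    step <- max(min(r / slope, 0.5), -0.5)
    ph2 <- ph - step
    r2 <- f(ph2)
    if (!is.finite(r2) || abs(r2) >= abs(r)) break
    ph <- ph2
    r <- r2
  }
  if (abs(r) > resid_tol) {
    # very poorly buffered solutions: fall back to a bisection refinement
    # around the current estimate to guarantee the residual tolerance
    a <- ph - 1e-6; b <- ph + 1e-6
    if (f(a) > 0 && f(b) < 0) {
      ph <- stats::uniroot(f, c(a, b), tol = 1e-15)$root
    }
  }
  ph
}

#' Equilibrium speciation with charge-balance pH
#'
#' Computes the unique speciation of the carbonate and sulfide systems that
#' satisfies all mass-action laws, the component mass balances, and the
#' charge balance, together with Davies activity corrections. The activity
#' coefficients and the pH are iterated to a joint fixed point.
#'
#' @param state A [solution_state()].
#' @param constants An [equilibrium_constants()] object.
#' @param ideal If `TRUE`, all activity coefficients are forced to 1.
#' @param fixed_ph If non-`NULL`, skip the charge-balance solve and speciate
#'   at this externally clamped pH (the returned residual is then generally
#'   non-zero).
#' @param include_s2 Include the S2- species (negligible below pH 12;
#'   off by default).
#' @param start Optional pH starting guess (warm start for repeated calls).
#' @return An object of class `speciation_result`: list with `ph`, species
#'   concentrations (`h`, `oh`, `co2`, `hco3`, `co3`, `h2s`, `hs`, `s2`,
#'   mol/L), `gamma` (named coefficients for z = 0, 1, 2), `activities`
#'   (named: `h`, `oh`, `hco3`, `co3`, `hs`, `mg`, `ca`, `so4`),
#'   `ionic_strength`, `clamped` (Davies cap hit), `residual` (mol/L),
#'   `iterations`, and the input `totals`.
#' @export
#' @examples
#' sp <- speciate(solution_state(dic = 1e-3, na = 1e-3))
#' sp$ph
speciate <- function(state, constants = equilibrium_constants(),
                     ideal = FALSE, fixed_ph = NULL, include_s2 = FALSE,
                     start = NULL) {
  stopifnot(inherits(state, "solution_state"))
  tot <- lapply(state[c("dic", "sulfide", "sulfate", "thiosulfate",
                        "mg", "ca", "na", "cl")], function(x) max(x, 0))
  .speciate_core(tot, constants, ideal = ideal, fixed_ph = fixed_ph,
                 include_s2 = include_s2, start = start)
}

# Core speciation fixed-point loop on plain totals (list with dic, sulfide,
# sulfate, thiosulfate, mg, ca, na, cl). Used directly by the reactor
# right-hand sides, which clamp and assemble totals themselves.
.speciate_core <- function(tot, k, ideal = FALSE, fixed_ph = NULL,
                           include_s2 = FALSE, start = NULL) {
  g1 <- 1; g2 <- 1
  I <- 0; clamped <- FALSE
  ph <- if (!is.null(start)) start else 7
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ph_new <- if (is.null(fixed_ph)) {
      .solve_ph(tot, k, g1, g2, include_s2, start = ph)
    } else fixed_ph
    sp <- .species_at(10^(-ph_new), tot, k, g1, g2, include_s2)
    I_new <- 0.5 * (4 * tot$mg + 4 * tot$ca + tot$na + tot$cl +
                      4 * tot$sulfate + 4 * tot$thiosulfate +
                      sp$h + sp$oh + sp$hco3 + 4 * sp$co3 + sp$hs + 4 * sp$s2)
    if (ideal) { ph <- ph_new; I <- I_new; break }
    gg <- activity_coefficients(I_new, c(1, 2), constants = k, warn = FALSE)
    done <- abs(ph_new - ph) < 1e-8 && abs(I_new - I) < 1e-8 * (1 + I_new) &&
      iter > 1L
    ph <- ph_new; I <- I_new
    clamped <- I_new > k$I_cap
    g1 <- gg[1]; g2 <- gg[2]
    if (done || iter >= 60L) break
  }
  if (iter >= 60L && is.null(fixed_ph)) {
    stop("speciation did not converge (activity/pH fixed point)")
  }
  sp <- .species_at(10^(-ph), tot, k, g1, g2, include_s2)
  act <- c(h = 10^(-ph), oh = g1 * sp$oh, hco3 = g1 * sp$hco3,
           co3 = g2 * sp$co3, hs = g1 * sp$hs,
           mg = g2 * tot$mg, ca = g2 * tot$ca, so4 = g2 * tot$sulfate)
  out <- list(ph = ph, h = sp$h, oh = sp$oh, co2 = sp$co2, hco3 = sp$hco3,
              co3 = sp$co3, h2s = sp$h2s, hs = sp$hs, s2 = sp$s2,
              gamma = c(`0` = 1, `1` = g1, `2` = g2),
              activities = act, ionic_strength = I, clamped = clamped,
              residual = sp$resid, iterations = iter,
              totals = unlist(tot))
  class(out) <- "speciation_result"
  out
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("speciation: pH %.4f, I %.4g mol/L%s, residual %.2e mol/L\n",
              x$ph, x$ionic_strength,
              if (x$clamped) " (Davies cap)" else "", x$residual))
  invisible(x)
}

#' Mineral saturation index
#'
#' Ratio of the ion-activity product to the solubility product,
#' `Omega = IAP / Ksp`. `Omega > 1` indicates supersaturation (driving
#' precipitation for MgCO3 seeds), `Omega = 1` equilibrium.
#'
#' @param spec A [speciate()] result.
#' @param constants An [equilibrium_constants()] object.
#' @param mineral One of `"magnesite"`, `"calcite"`, `"dolomite"`,
#'   `"gypsum"`, `"brucite"`.
#' @return Dimensionless saturation index (>= 0).
#' @export
#' @examples
#' sp <- speciate(solution_state(dic = 1e-2, mg = 1e-2, na = 2e-2))
#' saturation_index(sp, mineral = "magnesite")
saturation_index <- function(spec, constants = equilibrium_constants(),
                             mineral = "magnesite") {
  stopifnot(inherits(spec, "speciation_result"))
  a <- spec$activities
  iap <- switch(mineral,
    magnesite = a[["mg"]] * a[["co3"]],
    calcite   = a[["ca"]] * a[["co3"]],
    dolomite  = a[["ca"]] * a[["mg"]] * a[["co3"]]^2,
    gypsum    = a[["ca"]] * a[["so4"]],
    brucite   = a[["mg"]] * a[["oh"]]^2,
    stop("unknown mineral: ", mineral)
  )
  unname(iap / constants$Ksp[[mineral]])
}

#' Convert between mg/L and mol/L
#'
#' Boundary unit helpers: biomass and dissolved-oxygen kinetics use mg/L
#' while all internal chemistry is in mol/L.
#'
#' @param x Concentration to convert.
#' @param molar_mass Molar mass in g/mol.
#' @return Converted concentration.
#' @export
mg_per_l_to_mol <- function(x, molar_mass) x / 1000 / molar_mass

#' @rdname mg_per_l_to_mol
#' @export
mol_to_mg_per_l <- function(x, molar_mass) x * 1000 * molar_mass
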