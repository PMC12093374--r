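# Growth and conversion rate laws for the two organisms of the sulfur cycle:
# an aerobic sulfur oxidizer (A. thiooxidans-like) and an anaerobic sulfate
# reducer (D. vulgaris-like) growing on dissolved hydrogen.

# molar masses of the reduced-S substrates, g/mol
.M_SUBSTRATE <- c(h2s = 34.08, s2o3 = 112.13)

#' Kinetic parameters of the sulfur oxidizer
#'
#' The substrate half-saturation constant `K_S` is substrate-specific: the
#' registry carries one value for thiosulfate and a much smaller one for
#' dissolved H2S (which is only ever present at trace levels under a dilute
#' gas feed).
#'
#' @param overrides Named list of replacements (e.g. `list(mu_max = 0.05)`).
#' @param substrate `"s2o3"` or `"h2s"`; selects the registry `K_S` default.
#' @param registry Registry list from [load_registry()].
#' @return Object of class `oxidizer_params`: `mu_max` (1/h), `k_d` (1/h),
#'   `K_S` (mg/L, reduced-sulfur half-saturation), `K_O` (mg/L, oxygen
#'   kinetic constant), `yield` (mg biomass per mg substrate).
#' @export
oxidizer_params <- function(overrides = NULL, substrate = c("s2o3", "h2s"),
                            registry = load_registry()) {
  substrate <- match.arg(substrate)
  p <- registry$organisms$oxidizer
  p$K_S <- if (substrate == "h2s") p$K_S_h2s else p$K_S_s2o3
  p$K_S_h2s <- p$K_S_s2o3 <- NULL
  if (!is.null(overrides)) p <- modify_list_deep(p, overrides)
  stopifnot(all(unlist(p[c("mu_max", "k_d", "K_S", "K_O", "yield")]) > 0))
  class(p) <- "oxidizer_params"
  p
}

#' Kinetic parameters of the sulfate reducer
#'
#' @inheritParams oxidizer_params
#' @return Object of class `reducer_params`: `mu_max_S` (1/h), `k_d` (1/h),
#'   `K_S_sulfate` (mol/L), `K_H` (mol/L), `Y_S` (g biomass per mol sulfate).
#' @export
reducer_params <- function(overrides = NULL, registry = load_registry()) {
  p <- registry$organisms$reducer
  if (!is.null(overrides)) p <- modify_list_deep(p, overrides)
  stopifnot(all(unlist(p[c("mu_max_S", "k_d", "K_S_sulfate", "K_H", "Y_S")]) > 0))
  class(p) <- "reducer_params"
  p
}

#' Sulfur-oxidizer growth and conversion rates
#'
#' Dual-Monod growth model: `dX/dt = mu_max * gamma * X - k_d * X` with
#' `gamma = C_LS/(K_S + C_LS) * C_LO/(K_O + C_LO)`. Substrate oxidation is
#' tied to gross growth through the biomass yield; reaction stoichiometry
#' couples it to O2 consumption, sulfate production, and proton release:
#' per mol H2S oxidized, 2 O2 consumed and 1 SO4-- + 2 H+ produced; per mol
#' thiosulfate, 2 O2 consumed and 2 SO4-- + 2 H+ produced.
#'
#' @param X Biomass (mg dry weight / L).
#' @param C_LS Dissolved substrate concentration (mg/L of H2S or S2O3--).
#' @param C_LO Dissolved oxygen (mg/L).
#' @param params An [oxidizer_params()] object.
#' @param cycle_variant `"h2s"` or `"s2o3"`.
#' @param modifier Optional extra multiplicative rate modifier in `[0, 1]`
#'   (hook for a lag/inhibition term; default identity).
#' @return List of class `growth_rates`: `gamma` (dimensionless, in `[0,1]`),
#'   `dX` (mg/L/h net), `growth` (mg/L/h gross), `substrate_mg` (mg/L/h,
#'   consumption >= 0), `substrate_mol` (mol/L/h), `o2_mol` (mol/L/h
#'   consumption), `sulfate_mol` (mol/L/h production), `proton_mol` (mol/L/h
#'   production).
#' @export
#' @examples
#' p <- oxidizer_params()
#' oxidizer_rates(10, C_LS = p$K_S, C_LO = p$K_O, params = p,
#'                cycle_variant = "s2o3")$gamma  # 0.25
oxidizer_rates <- function(X, C_LS, C_LO, params,
                           cycle_variant = c("s2o3", "h2s"),
                           modifier = 1) {
  cycle_variant <- match.arg(cycle_variant)
  if (any(c(X, C_LS, C_LO) < 0)) stop("oxidizer_rates: inputs must be >= 0")
  stopifnot(inherits(params, "oxidizer_params"))
  gamma <- (C_LS / (params$K_S + C_LS)) * (C_LO / (params$K_O + C_LO)) * modifier
  growth <- params$mu_max * gamma * X
  dX <- growth - params$k_d * X
  sub_mg <- growth / params$yield
  sub_mol <- mg_per_l_to_mol(sub_mg, .M_SUBSTRATE[[cycle_variant]])
  n_so4 <- if (cycle_variant == "h2s") 1 else 2
  out <- list(gamma = gamma, dX = dX, growth = growth,
              substrate_mg = sub_mg, substrate_mol = sub_mol,
              o2_mol = 2 * sub_mol,
              sulfate_mol = n_so4 * sub_mol,
              proton_mol = 2 * sub_mol)
  class(out) <- "growth_rates"
  out
}

#' Sulfate-reducer growth and conversion rates
#'
#' Dual-Monod sulfate reduction on dissolved hydrogen:
#' `r_X = mu_max_S * X * S/(K_S + S) * C_LH/(K_H + C_LH)` (g/L/h gross
#' growth), `dX/dt = r_X - k_d X`, and sulfate consumption `r_S = r_X / Y_S`.
#' Stoichiometry: reduction to H2S consumes 4 H2 and 2 H+ per sulfate;
#' reduction to thiosulfate consumes 2 H2 and 1 H+ per sulfate and yields
#' 0.5 S2O3-- per sulfate.
#'
#' @param X Biomass (g/L).
#' @param S Sulfate (mol/L).
#' @param C_LH Dissolved hydrogen (mol/L).
#' @param params A [reducer_params()] object.
#' @param cycle_variant `"h2s"` or `"s2o3"` (the reduced product).
#' @param modifier Optional extra multiplicative rate modifier (default 1).
#' @return List of class `growth_rates`: `gamma`, `r_X` (g/L/h), `dX`
#'   (g/L/h net), `r_S` (mol/L/h sulfate consumption), `h2_mol` (mol/L/h H2
#'   consumption), `product_mol` (mol/L/h H2S or S2O3-- production),
#'   `proton_mol` (mol/L/h H+ consumption).
#' @export
#' @examples
#' p <- reducer_params()
#' reducer_rates(1, S = p$K_S_sulfate, C_LH = p$K_H, params = p,
#'               cycle_variant = "h2s")$r_X  # 0.25 * mu_max_S
reducer_rates <- function(X, S, C_LH, params,
                          cycle_variant = c("h2s", "s2o3"),
                          modifier = 1) {
  cycle_variant <- match.arg(cycle_variant)
  if (any(c(X, S, C_LH) < 0)) stop("reducer_rates: inputs must be >= 0")
  stopifnot(inherits(params, "reducer_params"))
  gamma <- (S / (params$K_S_sulfate + S)) * (C_LH / (params$K_H + C_LH)) * modifier
  r_X <- params$mu_max_S * gamma * X
  dX <- r_X - params$k_d * X
  r_S <- r_X / params$Y_S
  if (cycle_variant == "h2s") {
    h2 <- 4 * r_S; product <- r_S; protons <- 2 * r_S
  } else {
    h2 <- 2 * r_S; product <- 0.5 * r_S; protons <- 1 * r_S
  }
  out <- list(gamma = gamma, r_X = r_X, dX = dX, r_S = r_S,
              h2_mol = h2, product_mol = product, proton_mol = protons)
  class(out) <- "growth_rates"
  out
}

#' Calibrate the oxidizer maximum specific growth rate
#'
#' Least-squares fit of a simulated biomass trajectory to observed biomass
#' data, varying only `mu_max`. The fit is performed on the log scale by
#' default (appropriate for multiplicative measurement noise). A profile
#' (F-statistic) confidence interval is reported.
#'
#' @param data Data frame with columns `time` (h) and `biomass` (same units
#'   the simulator returns); at least 4 positive observations.
#' @param simulator Function `f(mu_max, times)` returning the simulated
#'   biomass at `times`. Defaults to the biomass trajectory of the
#'   tailings-dissolution validation scenario (see
#'   [validation_biomass_simulator()]).
#' @param interval Search interval for `mu_max` (1/h).
#' @param log_scale Fit on log-transformed biomass (default `TRUE`).
#' @param ci Compute a 95% profile confidence interval (default `TRUE`).
#' @return Object of class `mu_max_fit`: `mu_max` (1/h), `sse`,
#'   `residual_norm`, `ci` (length-2 vector or `NULL`), `n`, `log_scale`.
#' @export
calibrate_mu_max <- function(data, simulator = NULL,
                             interval = c(1e-3, 0.1),
                             log_scale = TRUE, ci = TRUE) {
  stopifnot(is.data.frame(data), all(c("time", "biomass") %in% names(data)))
  data <- data[is.finite(data$biomass) & data$biomass > 0, ]
  n <- nrow(data)
  if (n < 2) stop("calibration needs at least 2 positive biomass observations")
  if (n < 4) {
    warning("fewer than 4 biomass observations; mu_max may be non-identifiable")
    ci <- FALSE
  }
  if (stats::sd(data$biomass) / mean(data$biomass) < 1e-10) {
    warning("biomass observations are flat; mu_max is not identifiable")
  }
  if (is.null(simulator)) simulator <- validation_biomass_simulator()
  obs <- if (log_scale) log(data$biomass) else data$biomass
  sse <- function(mu) {
    sim <- simulator(mu, data$time)
    sim <- pmax(sim, .Machine$double.xmin)
    pred <- if (log_scale) log(sim) else sim
    sum((obs - pred)^2)
  }
  opt <- stats::optimize(sse, interval = interval, tol = 1e-7)
  mu_hat <- opt$minimum
  sse_min <- opt$objective
  rel_margin <- min(mu_hat - interval[1], interval[2] - mu_hat) / diff(interval)
  if (rel_margin < 1e-3) {
    warning("mu_max estimate at the boundary of the search interval; ",
            "fit may be non-identifiable")
  }
  ci_out <- NULL
  if (ci && n > 2) {
    thr <- sse_min * (1 + stats::qf(0.95, 1, n - 1) / (n - 1))
    g <- function(mu) sse(mu) - thr
    lo <- if (g(interval[1]) > 0) {
      stats::uniroot(g, c(interval[1], mu_hat), tol = 1e-7)$root
    } else interval[1]
    hi <- if (g(interval[2]) > 0) {
      stats::uniroot(g, c(mu_hat, interval[2]), tol = 1e-7)$root
    } else interval[2]
    ci_out <- c(lower = lo, upper = hi)
  }
  out <- list(mu_max = mu_hat, sse = sse_min,
              residual_norm = sqrt(sse_min), ci = ci_out, n = n,
              log_scale = log_scale)
  class(out) <- "mu_max_fit"
  out
}

#' @export
print.mu_max_fit <- function(x, ...) {
  cat(sprintf("mu_max = %.5f 1/h (n = %d, residual norm %.3g)\n",
              x$mu_max, x$n, x$residual_norm))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% profile CI: [%.5f, %.5f]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}
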