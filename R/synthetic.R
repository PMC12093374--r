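# Pseudo-experimental datasets with the statistical structure of the
# tailings-dissolution validation study: time series of microbial density,
# dissolved Ca2+ and Mg2+, and pH from a static culture, sampled at a fixed
# cadence with measurement noise. Concentration-like observables get
# median-unbiased multiplicative lognormal noise; pH gets additive Gaussian
# noise.

#' Measurement-noise model
#'
#' @param sigma Named lognormal sigmas for the multiplicative observables
#'   (`biomass`, `ca`, `mg`); dimensionless (log scale).
#' @param sigma_ph Additive Gaussian standard deviation for pH.
#' @param times Sampling times (h), strictly increasing.
#' @param seed Integer RNG seed.
#' @param missingness Fraction of observations dropped at random, in `[0, 1)`.
#' @return Object of class `noise_model`.
#' @export
#' @examples
#' nm <- noise_model(seed = 42)
noise_model <- function(sigma = c(biomass = 0.05, ca = 0.05, mg = 0.05),
                        sigma_ph = 0.1, times = seq(0, 500, by = 24),
                        seed = 1, missingness = 0) {
  stopifnot(all(sigma >= 0), sigma_ph >= 0, all(diff(times) > 0),
            missingness >= 0, missingness < 1)
  out <- list(sigma = sigma, sigma_ph = sigma_ph, times = times,
              seed = as.integer(seed), missingness = missingness)
  class(out) <- "noise_model"
  out
}

#' Generate a synthetic validation dataset
#'
#' Runs the tailings-dissolution validation scenario at the given "true"
#' parameters, samples the four observables at the noise model's times, and
#' applies measurement noise: `value = trajectory * exp(sigma * Z)` for
#' biomass/Ca/Mg (median-unbiased lognormal) and `value = trajectory +
#' sigma_ph * Z` for pH (truncated to `[0, 14]`). Fully reproducible given
#' the seed; replicates share the single underlying trajectory and differ
#' only in noise.
#'
#' @param scen A [validation_scenario()].
#' @param true_params Named list of oxidizer-parameter overrides treated as
#'   the generating truth (e.g. `list(mu_max = 0.0117)`).
#' @param noise A [noise_model()].
#' @param replicates Number of noise replicates.
#' @return Data frame of class `synthetic_dataset` with columns `time`,
#'   `observable` (`biomass`, `ca`, `mg`, `ph`), `value`, `replicate`;
#'   attributes `true_params` and `noise`.
#' @export
#' @examples
#' \donttest{
#' ds <- generate_synthetic(noise = noise_model(times = seq(0, 96, 24)))
#' }
generate_synthetic <- function(scen = validation_scenario(),
                               true_params = list(mu_max = 0.0117),
                               noise = noise_model(), replicates = 1) {
  stopifnot(inherits(noise, "noise_model"))
  for (nm in names(true_params)) scen$oxidizer[[nm]] <- true_params[[nm]]
  scen$max_time <- max(noise$times)
  tr <- run_validation_scenario(scen, radii = scen$populations[[1]]$radius)
  at <- function(col) stats::approx(tr$time, tr[[col]], xout = noise$times,
                                    rule = 2)$y
  truth <- list(biomass = at("biomass_g_l"), ca = at("ca_mg_l"),
                mg = at("mg_mg_l"), ph = at("ph"))
  nt <- length(noise$times)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(noise$seed)
  rows <- list()
  for (rep in seq_len(replicates)) {
    for (obs in c("biomass", "ca", "mg")) {
      v <- truth[[obs]] * exp(noise$sigma[[obs]] * stats::rnorm(nt))
      rows[[length(rows) + 1L]] <- data.frame(
        time = noise$times, observable = obs, value = v, replicate = rep)
    }
    v <- pmin(pmax(truth$ph + noise$sigma_ph * stats::rnorm(nt), 0), 14)
    rows[[length(rows) + 1L]] <- data.frame(
      time = noise$times, observable = "ph", value = v, replicate = rep)
  }
  out <- do.call(rbind, rows)
  if (noise$missingness > 0) {
    keep <- stats::runif(nrow(out)) >= noise$missingness
    out <- out[keep, ]
  }
  rownames(out) <- NULL
  structure(out, class = c("synthetic_dataset", "data.frame"),
            true_params = true_params, noise = noise)
}

#' Write a synthetic dataset as CSV with a YAML provenance sidecar
#'
#' @param dataset A [generate_synthetic()] result.
#' @param path CSV output path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  nm <- attr(dataset, "noise")
  meta <- list(true_params = attr(dataset, "true_params"),
               noise = list(sigma = as.list(nm$sigma), sigma_ph = nm$sigma_ph,
                            times = nm$times, seed = nm$seed,
                            missingness = nm$missingness))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Growth-rate recovery experiment
#'
#' End-to-end check of the calibration procedure: generate `n` synthetic
#' biomass datasets at a known maximum specific growth rate, refit `mu_max`
#' on each with [calibrate_mu_max()], and summarize the recovery.
#'
#' @param true_mu_max Generating value (1/h).
#' @param noise A [noise_model()]; its seed anchors the experiment, each
#'   replicate uses `seed + replicate index`.
#' @param n Number of replicates (>= 1).
#' @param scen A [validation_scenario()] used both to generate and to fit.
#' @param interval Search interval for the fit.
#' @param ci Compute profile intervals (needed for coverage; slower).
#' @return Object of class `recovery_report`: `estimates` (numeric vector),
#'   `true_mu_max`, `bias`, `rmse`, `mean_rel_error`, `coverage` (fraction
#'   of 95% intervals containing the truth, `NA` if `ci = FALSE`).
#' @export
recovery_experiment <- function(true_mu_max = 0.0117, noise = noise_model(),
                                n = 5, scen = validation_scenario(),
                                interval = c(1e-3, 0.1), ci = FALSE) {
  stopifnot(n >= 1)
  simulator <- validation_biomass_simulator(scen)
  est <- numeric(n)
  covered <- logical(n)
  for (i in seq_len(n)) {
    nm_i <- noise
    nm_i$seed <- noise$seed + i
    ds <- generate_synthetic(scen, true_params = list(mu_max = true_mu_max),
                             noise = nm_i)
    bio <- ds[ds$observable == "biomass", ]
    fit <- calibrate_mu_max(data.frame(time = bio$time, biomass = bio$value),
                            simulator = simulator, interval = interval,
                            ci = ci)
    est[i] <- fit$mu_max
    covered[i] <- if (ci && !is.null(fit$ci)) {
      fit$ci[1] <= true_mu_max && true_mu_max <= fit$ci[2]
    } else NA
  }
  out <- list(estimates = est, true_mu_max = true_mu_max,
              bias = mean(est) - true_mu_max,
              rmse = sqrt(mean((est - true_mu_max)^2)),
              mean_rel_error = mean(abs(est - true_mu_max)) / true_mu_max,
              coverage = if (ci) mean(covered) else NA_real_)
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "mu_max recovery: truth %.5f, mean estimate %.5f (bias %+.2e, RMSE %.2e, mean |rel err| %.2f%%)\n",
    x$true_mu_max, mean(x$estimates), x$bias, x$rmse, 100 * x$mean_rel_error))
  if (!is.na(x$coverage)) cat(sprintf("  interval coverage: %.0f%%\n",
                                      100 * x$coverage))
  invisible(x)
}
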