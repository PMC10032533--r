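# Calibration stage: estimate the volumetric force constant F_vol from
# spheres in a fluid of known viscosity. The Stokes-drag relation
# F_vol = 18*mu*v_hat/D^2 implies v_hat is linear in the squared sphere
# radius; a Bayesian no-intercept regression of v_hat on r^2 pools all
# spheres into one slope beta, and F_vol = (9/2)*beta*mu.

jags_chain_inits <- function(mcmc) {
  lapply(seq_len(mcmc$chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mcmc$seed + c) %% 2147483647L)
  })
}

run_jags <- function(model_string, data, monitors, mcmc) {
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          n.chains = mcmc$chains, n.adapt = mcmc$warmup,
                          inits = jags_chain_inits(mcmc), quiet = TRUE)
  # burn-in beyond adaptation, same length as the adaptation window
  stats::update(jm, n.iter = mcmc$warmup, progress.bar = "none")
  rjags::coda.samples(jm, variable.names = monitors, n.iter = mcmc$iter * mcmc$thin,
                      thin = mcmc$thin, progress.bar = "none")
}

calibration_model_string <- function() {
  # prior: sigma = sigma_scale * x with x ~ InverseGamma(ig_shape, ig_second);
  # sampled through 1/x ~ Gamma(ig_shape, rate = ig_rate) where ig_rate is the
  # scale (default reading) or the reciprocal rate of the inverse gamma.
  paste0(
    "model {\n",
    "  beta ~ dnorm(0, pow(beta_prior_sd, -2))\n",
    "  xinv ~ dgamma(ig_shape, ig_rate)\n",
    "  sigma <- sigma_scale / xinv\n",
    "  tau <- pow(sigma, -2)\n",
    "  for (i in 1:N) {\n",
    "    v[i] ~ dnorm(beta * r2[i], tau)\n",
    "  }\n",
    "}\n")
}

#' Bayesian calibration of the volumetric force constant
#'
#' Fits the no-intercept regression `v_hat ~ N(beta * r^2, sigma^2)` with
#' priors `beta ~ N(0, 5000)` (SD) and `sigma = 1e-8 * x`,
#' `x ~ InverseGamma(0.5, 1)` — priors on SI scales (m/s against m^2) — and
#' derives `F_vol = (9/2) * beta * mu` draw-wise. Goodness of fit is
#' summarized with a Bayesian R^2 (draw-wise explained-variance fraction).
#'
#' @param radius_m Sphere radii (m).
#' @param velocity_m_s Fitted velocity amplitudes (m/s).
#' @param fluid A [fluid_properties()] object.
#' @param mcmc An [mcmc_config()].
#' @param beta_prior_sd Prior SD for the slope (default 5000).
#' @param sigma_prior_scale Multiplicative scale applied to the
#'   inverse-gamma noise prior (default 1e-8; a knob to match data scale).
#' @param ig_shape,ig_second Shape and second parameter of the inverse-gamma
#'   prior on the (unscaled) noise SD (defaults 0.5 and 1).
#' @param sigma_parametrization `"scale"` (default) treats `ig_second` as a
#'   scale, `"rate"` as a rate (the two coincide at the default value 1).
#' @return Object of class `calibration_fit`: posterior draw vectors for
#'   `beta`, `sigma` and `f_volumetric`, their summaries, `bayes_r2`,
#'   per-parameter diagnostics (`rhat`, `ess`), a `converged` flag and the
#'   input data.
#' @export
fit_volumetric_force <- function(radius_m, velocity_m_s, fluid,
                                 mcmc = mcmc_config(),
                                 beta_prior_sd = 5000,
                                 sigma_prior_scale = 1e-8,
                                 ig_shape = 0.5, ig_second = 1,
                                 sigma_parametrization = c("scale", "rate")) {
  sigma_parametrization <- match.arg(sigma_parametrization)
  check_positive(ig_shape, "ig_shape")
  check_positive(ig_second, "ig_second")
  stopifnot(inherits(fluid, "fluid_properties"), inherits(mcmc, "mcmc_config"))
  abort_if(length(radius_m) < 2, "calibration needs at least 2 spheres")
  abort_if(length(radius_m) != length(velocity_m_s),
           "radius and velocity vectors differ in length")
  check_positive(radius_m, "radius_m")
  abort_if(any(!is.finite(velocity_m_s)), "velocity_m_s must be finite")
  mu <- fluid$dynamic_viscosity_pa_s

  data <- list(v = as.numeric(velocity_m_s), r2 = as.numeric(radius_m)^2,
               N = length(radius_m), beta_prior_sd = beta_prior_sd,
               sigma_scale = sigma_prior_scale, ig_shape = ig_shape,
               ig_rate = if (sigma_parametrization == "scale") ig_second
                         else 1 / ig_second)
  samples <- run_jags(calibration_model_string(), data,
                      c("beta", "sigma"), mcmc)
  draws <- as.matrix(samples)
  beta <- draws[, "beta"]; sigma <- draws[, "sigma"]
  f_vol <- 4.5 * beta * mu

  diag <- mcmc_diagnostics(samples)
  r2 <- bayes_r2_draws(beta, sigma, data$r2)
  structure(list(
    draws = list(beta = beta, sigma = sigma, f_volumetric = f_vol),
    beta_mean = mean(beta), beta_sd = stats::sd(beta),
    f_volumetric_mean = mean(f_vol), f_volumetric_sd = stats::sd(f_vol),
    f_volumetric_ci95 = unname(stats::quantile(f_vol, c(0.025, 0.975))),
    sigma_mean = mean(sigma),
    bayes_r2 = mean(r2), bayes_r2_draws = r2,
    diagnostics = diag, converged = diag$verdict,
    dynamic_viscosity_pa_s = mu,
    data = data.frame(radius_m = radius_m, velocity_m_s = velocity_m_s),
    mcmc = mcmc), class = "calibration_fit")
}

# Draw-wise Bayesian R^2: var(fitted) / (var(fitted) + sigma^2).
bayes_r2_draws <- function(beta, sigma, r2_predictor) {
  vapply(seq_along(beta), function(d) {
    pred <- beta[d] * r2_predictor
    vp <- stats::var(pred)
    vp / (vp + sigma[d]^2)
  }, numeric(1))
}

#' Bayesian R-squared of a calibration fit
#'
#' Posterior mean of the draw-wise explained-variance fraction
#' `var(fitted) / (var(fitted) + sigma^2)`.
#'
#' @param fit A `calibration_fit`.
#' @return Scalar in \[0, 1\] (0, with a warning, for zero-variance data).
#' @export
bayesian_r2 <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (stats::var(fit$data$radius_m^2) == 0 || all(fit$draws$beta == 0)) {
    warning("degenerate zero-variance predictor; Bayesian R^2 defined as 0",
            call. = FALSE)
    return(0)
  }
  fit$bayes_r2
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Volumetric force calibration (%d spheres, mu = %g Pa s)\n",
              nrow(x$data), x$dynamic_viscosity_pa_s))
  cat(sprintf("  beta  : %.4g +/- %.3g (m/s per m^2)\n", x$beta_mean, x$beta_sd))
  cat(sprintf("  F_vol : %.4g +/- %.3g N/m^3   (95%% CI %.4g..%.4g)\n",
              x$f_volumetric_mean, x$f_volumetric_sd,
              x$f_volumetric_ci95[1], x$f_volumetric_ci95[2]))
  cat(sprintf("  Bayes R2: %.4f | max Rhat %.3f | converged: %s\n",
              x$bayes_r2, max(x$diagnostics$rhat, na.rm = TRUE), x$converged))
  invisible(x)
}

#' Per-sphere volumetric force constant (Stokes drag)
#'
#' Direct single-sphere estimate `F_vol = 18 * mu * v_hat / D^2` with
#' `D = 2 r`; less robust than the pooled regression but useful as a
#' cross-check.
#'
#' @param radius_m Sphere radius (m).
#' @param velocity_m_s Velocity amplitude (m/s).
#' @param fluid A [fluid_properties()] object.
#' @return Volumetric force constant(s) in N/m^3.
#' @export
per_sphere_force_constant <- function(radius_m, velocity_m_s, fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  check_positive(radius_m, "radius_m")
  18 * fluid$dynamic_viscosity_pa_s * velocity_m_s / (2 * radius_m)^2
}

#' Phase-angle summary over fitted spheres
#'
#' In a purely viscous calibration fluid the displacement lags the force by a
#' quarter period, so per-sphere phase angles should scatter around 90
#' degrees; their distribution summarizes measurement uncertainty.
#'
#' @param fits Fit table with `sphere` and `phase_deg` columns (repeats are
#'   averaged per sphere).
#' @return List with `per_sphere` (sphere, mean phase) and `summary`
#'   (mean, median, quartiles, SD, n).
#' @export
phase_angle_summary <- function(fits) {
  check_columns(fits, c("sphere", "phase_deg"), "fits")
  abort_if(nrow(fits) < 1, "at least one fit is required")
  per <- stats::aggregate(phase_deg ~ sphere, data = fits, FUN = mean)
  q <- stats::quantile(per$phase_deg, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_sphere = per,
       summary = c(mean = mean(per$phase_deg), median = q[2],
                   q25 = q[1], q75 = q[3],
                   sd = stats::sd(per$phase_deg), n = nrow(per)))
}
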