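# Bayesian multilevel heterogeneity model. One matrix type's observations
# are modeled as a nested chain of partially pooled level effects
# (matrix -> sample -> holder -> sphere) in non-centered form, with
# sphere-specific measurement-noise SDs partially pooled through an
# inverse-gamma whose shape (mean-noise hyperparameter) is shared across
# matrix types and whose scale is matrix-specific. Heterogeneity is the
# scale that scatters sphere means within a holder.

#' Z-score normalization with per-matrix means and one shared SD
#'
#' Centers each matrix type at its own mean but divides every matrix by the
#' same SD (computed once from the pooled, per-matrix-centered observations),
#' so heterogeneity scales stay comparable across matrix types while the
#' (irrelevant) property magnitudes are removed.
#'
#' @param observations Observation table (schema of
#'   [tracks_to_observations()]); needs >= 2 observations per matrix.
#' @param response Response column: `"abs_shear_modulus_pa"` or `"phase_deg"`.
#' @return Object of class `normalized_obs`: `data` (hierarchy labels plus
#'   normalized `y`), `response`, `raw_means` (named per matrix),
#'   `shared_sd`.
#' @export
normalize_observations <- function(observations,
                                   response = c("abs_shear_modulus_pa", "phase_deg")) {
  response <- match.arg(response)
  check_columns(observations,
                c("matrix", "sample", "holder", "location", "sphere", "repeat",
                  response), "observations")
  y_raw <- observations[[response]]
  abort_if(anyNA(y_raw), "response contains missing values")
  counts <- table(observations$matrix)
  abort_if(any(counts < 2), "every matrix needs >= 2 observations")
  means_arr <- tapply(y_raw, observations$matrix, mean)
  means <- stats::setNames(as.numeric(means_arr), names(means_arr))
  centered <- y_raw - means[observations$matrix]
  shared_sd <- stats::sd(centered)
  abort_if(!is.finite(shared_sd) || shared_sd == 0,
           "zero variance after centering: normalization undefined")
  data <- observations[c("matrix", "sample", "holder", "location", "sphere", "repeat")]
  data$y <- as.numeric(centered / shared_sd)
  structure(list(data = data, response = response,
                 raw_means = means, shared_sd = shared_sd),
            class = "normalized_obs")
}

#' Heterogeneity model specification
#'
#' @param variant One of `"primary"` (sample/holder/sphere levels),
#'   `"location_level"` (adds a location tier between holder and sphere),
#'   `"single_level"` (matrix mean + one scatter scale + pooled noise),
#'   `"pooled_baseline"` (single matrix mean whose scatter SD is the
#'   heterogeneity, pooled per-sphere noise retained) or
#'   `"pooled_no_shared_noise"` (the baseline without the pooled noise term).
#' @param response Response column the model is fitted to.
#' @param mcmc An [mcmc_config()].
#' @param noise_parametrization `"shape_scale"` (default) reads the
#'   per-sphere noise prior literally as InverseGamma(shape = shared
#'   mean-noise hyperparameter, scale = matrix-specific hyperparameter);
#'   `"mean_sd"` re-parametrizes it so the shared hyperparameter is the mean
#'   noise level and the matrix-specific one its SD.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(variant = c("primary", "location_level", "single_level",
                                   "pooled_baseline", "pooled_no_shared_noise"),
                       response = c("abs_shear_modulus_pa", "phase_deg"),
                       mcmc = mcmc_config(),
                       noise_parametrization = c("shape_scale", "mean_sd")) {
  structure(list(variant = match.arg(variant),
                 response = match.arg(response),
                 mcmc = mcmc,
                 noise_parametrization = match.arg(noise_parametrization)),
            class = "model_spec")
}

# Per-sphere noise block shared by the variants that keep pooled noise.
noise_block <- function(noise_parametrization, matrix_index_expr) {
  hyper <- if (noise_parametrization == "shape_scale") {
    paste0("  for (m in 1:M) { ig_shape_m[m] <- sigma_mu\n",
           "                   ig_rate_m[m] <- sigma_sigma[m] }\n")
  } else {
    # mean-parametrized: mean = sigma_mu, SD = sigma_sigma[m]
    paste0("  for (m in 1:M) {\n",
           "    ig_shape_m[m] <- 2 + pow(sigma_mu / sigma_sigma[m], 2)\n",
           "    ig_rate_m[m] <- sigma_mu * (ig_shape_m[m] - 1)\n",
           "  }\n")
  }
  list(hyper = paste0(
         "  sigma_mu ~ dnorm(0, 1) T(0,)\n",
         "  for (m in 1:M) { sigma_sigma[m] ~ dnorm(0, 1) T(0,) }\n",
         hyper),
       sphere = paste0(
         "    g_t[t] ~ dgamma(ig_shape_m[", matrix_index_expr, "], ",
         "ig_rate_m[", matrix_index_expr, "])\n",
         "    sigma_t[t] <- 1 / g_t[t]\n"))
}

#' Build a heterogeneity model variant
#'
#' Assembles the JAGS model code, monitored parameters and the mapping from
#' level names to scatter-scale parameters for a [model_spec()] variant.
#' Level names follow the level each scale scatters: `sample_within_matrix`
#' scatters sample means, `holder_within_sample` holder means, and
#' `sphere_within_holder` (or `sphere_within_location` plus
#' `location_within_holder` under the location variant) sphere means — the
#' last being the headline heterogeneity.
#'
#' @param spec A [model_spec()].
#' @return List with `variant`, `model_string`, `monitors`, `levels` (named
#'   character map level -> parameter) and `uses_location`.
#' @export
build_variant <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  v <- spec$variant
  nb <- noise_block(spec$noise_parametrization, "sphere_matrix[t]")
  header <- "model {\n"
  matrix_block <- "  for (m in 1:M) { mu_matrix[m] ~ dnorm(0, 1) }\n"

  if (v %in% c("primary", "location_level")) {
    scales <- c("scale_sample", "scale_holder", "scale_sphere",
                if (v == "location_level") "scale_location")
    scale_block <- paste0(
      "  for (m in 1:M) {\n",
      paste0("    ", scales, "[m] ~ dnorm(0, 1) T(0,)\n", collapse = ""),
      "  }\n")
    # The generative definition is non-centered (child mean = parent mean +
    # scale * standard-normal innovation). The sampler works on the
    # equivalent centered form — the efficient parametrization for a Gibbs
    # sampler — and the innovations z are reported as derived quantities.
    chain <- paste0(
      "  for (s in 1:NS) {\n",
      "    mu_sample[s] ~ dnorm(mu_matrix[sample_matrix[s]], pow(scale_sample[sample_matrix[s]], -2))\n",
      "    z_sample[s] <- (mu_sample[s] - mu_matrix[sample_matrix[s]]) / scale_sample[sample_matrix[s]]\n",
      "  }\n",
      "  for (h in 1:NH) {\n",
      "    mu_holder[h] ~ dnorm(mu_sample[holder_sample[h]], pow(scale_holder[holder_matrix[h]], -2))\n",
      "    z_holder[h] <- (mu_holder[h] - mu_sample[holder_sample[h]]) / scale_holder[holder_matrix[h]]\n",
      "  }\n")
    if (v == "location_level") {
      chain <- paste0(chain,
        "  for (l in 1:NL) {\n",
        "    mu_location[l] ~ dnorm(mu_holder[location_holder[l]], pow(scale_location[location_matrix[l]], -2))\n",
        "    z_location[l] <- (mu_location[l] - mu_holder[location_holder[l]]) / scale_location[location_matrix[l]]\n",
        "  }\n",
        "  for (t in 1:NT) {\n",
        "    mu_sphere[t] ~ dnorm(mu_location[sphere_location[t]], pow(scale_sphere[sphere_matrix[t]], -2))\n",
        "    z_sphere[t] <- (mu_sphere[t] - mu_location[sphere_location[t]]) / scale_sphere[sphere_matrix[t]]\n",
        nb$sphere,
        "  }\n")
      levels <- c(sample_within_matrix = "scale_sample",
                  holder_within_sample = "scale_holder",
                  location_within_holder = "scale_location",
                  sphere_within_location = "scale_sphere")
      monitors <- c("mu_matrix", "mu_sample", "mu_holder", "mu_location",
                    scales, "sigma_mu", "sigma_sigma", "sigma_t",
                    "z_sample", "z_holder", "z_location", "z_sphere")
    } else {
      chain <- paste0(chain,
        "  for (t in 1:NT) {\n",
        "    mu_sphere[t] ~ dnorm(mu_holder[sphere_holder[t]], pow(scale_sphere[sphere_matrix[t]], -2))\n",
        "    z_sphere[t] <- (mu_sphere[t] - mu_holder[sphere_holder[t]]) / scale_sphere[sphere_matrix[t]]\n",
        nb$sphere,
        "  }\n")
      levels <- c(sample_within_matrix = "scale_sample",
                  holder_within_sample = "scale_holder",
                  sphere_within_holder = "scale_sphere")
      monitors <- c("mu_matrix", "mu_sample", "mu_holder",
                    scales, "sigma_mu", "sigma_sigma", "sigma_t",
                    "z_sample", "z_holder", "z_sphere")
    }
    lik <- paste0(
      "  for (i in 1:N) {\n",
      "    y[i] ~ dnorm(mu_sphere[obs_sphere[i]], pow(sigma_t[obs_sphere[i]], -2))\n",
      "  }\n")
    model <- paste0(header, matrix_block, scale_block, nb$hyper, chain, lik, "}\n")
  } else if (v == "single_level") {
    model <- paste0(header, matrix_block,
      "  for (m in 1:M) { scale_sphere[m] ~ dnorm(0, 1) T(0,) }\n",
      nb$hyper,
      "  for (t in 1:NT) {\n",
      "    mu_sphere[t] ~ dnorm(mu_matrix[sphere_matrix[t]], pow(scale_sphere[sphere_matrix[t]], -2))\n",
      "    z_sphere[t] <- (mu_sphere[t] - mu_matrix[sphere_matrix[t]]) / scale_sphere[sphere_matrix[t]]\n",
      nb$sphere,
      "  }\n",
      "  for (i in 1:N) {\n",
      "    y[i] ~ dnorm(mu_sphere[obs_sphere[i]], pow(sigma_t[obs_sphere[i]], -2))\n",
      "  }\n}\n")
    levels <- c(sphere_within_matrix = "scale_sphere")
    monitors <- c("mu_matrix", "scale_sphere", "sigma_mu", "sigma_sigma",
                  "sigma_t", "z_sphere")
  } else if (v == "pooled_baseline") {
    model <- paste0(header, matrix_block,
      "  for (m in 1:M) { s_matrix[m] ~ dnorm(0, 1) T(0,) }\n",
      nb$hyper,
      "  for (t in 1:NT) {\n", nb$sphere, "  }\n",
      "  for (i in 1:N) {\n",
      "    y[i] ~ dnorm(mu_matrix[obs_matrix[i]], ",
      "1 / (pow(s_matrix[obs_matrix[i]], 2) + pow(sigma_t[obs_sphere[i]], 2)))\n",
      "  }\n}\n")
    levels <- c(pooled_sd = "s_matrix")
    monitors <- c("mu_matrix", "s_matrix", "sigma_mu", "sigma_sigma", "sigma_t")
  } else { # pooled_no_shared_noise
    model <- paste0(header, matrix_block,
      "  for (m in 1:M) { s_matrix[m] ~ dnorm(0, 1) T(0,) }\n",
      "  for (i in 1:N) {\n",
      "    y[i] ~ dnorm(mu_matrix[obs_matrix[i]], pow(s_matrix[obs_matrix[i]], -2))\n",
      "  }\n}\n")
    levels <- c(pooled_sd = "s_matrix")
    monitors <- c("mu_matrix", "s_matrix")
  }
  list(variant = v, model_string = model, monitors = monitors,
       levels = levels,
       uses_location = v == "location_level",
       uses_noise = v != "pooled_no_shared_noise")
}

# Index tables mapping hierarchy labels to consecutive JAGS indices.
build_index <- function(norm) {
  d <- norm$data
  abort_if(any(!nzchar(as.character(unlist(d[1:6])))),
           "hierarchy labels must be non-empty")
  matrices <- sort(unique(d$matrix))
  skey <- paste(d$matrix, d$sample, sep = "|")
  hkey <- paste(skey, d$holder, sep = "|")
  lkey <- paste(hkey, d$location, sep = "|")
  tkey <- paste(lkey, d$sphere, sep = "|")
  samples <- sort(unique(skey)); holders <- sort(unique(hkey))
  locations <- sort(unique(lkey)); spheres <- sort(unique(tkey))
  first_of <- function(keys, uniq) match(uniq, keys)
  sf <- first_of(skey, samples); hf <- first_of(hkey, holders)
  lf <- first_of(lkey, locations); tf <- first_of(tkey, spheres)
  list(
    matrices = matrices,
    samples = samples, holders = holders, locations = locations,
    spheres = spheres,
    sample_matrix = match(d$matrix[sf], matrices),
    holder_sample = match(skey[hf], samples),
    holder_matrix = match(d$matrix[hf], matrices),
    location_holder = match(hkey[lf], holders),
    location_matrix = match(d$matrix[lf], matrices),
    sphere_holder = match(hkey[tf], holders),
    sphere_location = match(lkey[tf], locations),
    sphere_matrix = match(d$matrix[tf], matrices),
    obs_sphere = match(tkey, spheres),
    obs_matrix = match(d$matrix, matrices))
}

jags_data_for <- function(variant_def, index, y) {
  data <- list(y = y, N = length(y), M = length(index$matrices),
               obs_matrix = index$obs_matrix)
  v <- variant_def$variant
  if (v %in% c("primary", "location_level", "single_level", "pooled_baseline")) {
    data$obs_sphere <- index$obs_sphere
    data$NT <- length(index$spheres)
    data$sphere_matrix <- index$sphere_matrix
  }
  if (v %in% c("primary", "location_level")) {
    data$NS <- length(index$samples); data$NH <- length(index$holders)
    data$sample_matrix <- index$sample_matrix
    data$holder_sample <- index$holder_sample
    data$holder_matrix <- index$holder_matrix
    if (v == "location_level") {
      data$NL <- length(index$locations)
      data$location_holder <- index$location_holder
      data$location_matrix <- index$location_matrix
      data$sphere_location <- index$sphere_location
    } else {
      data$sphere_holder <- index$sphere_holder
    }
  }
  # drop unused obs_matrix for variants whose likelihood is sphere-indexed
  if (v %in% c("primary", "location_level", "single_level")) data$obs_matrix <- NULL
  data
}

#' Fit the multilevel heterogeneity model
#'
#' Samples the posterior of the chosen model variant on normalized
#' observations. Degenerate designs (one holder per sample, one sphere per
#' holder) are permitted; the affected scale is then prior-dominated and an
#' identifiability warning is raised. The fit is flagged (with a warning,
#' not an error) when the maximum split R-hat reaches 1.05.
#'
#' @param norm A `normalized_obs` from [normalize_observations()].
#' @param spec A [model_spec()].
#' @return Object of class `heterogeneity_fit`: `draws` (merged draw matrix,
#'   chains stacked), `samples` (coda `mcmc.list`), `index` (label maps),
#'   `levels`, `spec`, normalization constants, `diagnostics` and
#'   `converged`.
#' @export
fit_heterogeneity <- function(norm, spec = model_spec()) {
  stopifnot(inherits(norm, "normalized_obs"), inherits(spec, "model_spec"))
  vd <- build_variant(spec)
  index <- build_index(norm)
  abort_if(vd$uses_location && any(!nzchar(norm$data$location)),
           "location-level variant requires location labels")
  if (spec$variant %in% c("primary", "location_level")) {
    per_sample_h <- table(index$holder_sample)
    per_holder_t <- table(index$sphere_holder)
    if (all(per_sample_h == 1) || (spec$variant == "primary" && all(per_holder_t == 1))) {
      warning("degenerate design: some level has a single child everywhere; ",
              "the corresponding scale is prior-dominated", call. = FALSE)
    }
  }
  data <- jags_data_for(vd, index, norm$data$y)
  samples <- run_jags(vd$model_string, data, vd$monitors, spec$mcmc)
  draws <- as.matrix(samples)
  diag <- mcmc_diagnostics(samples)
  if (!diag$verdict) {
    warning("MCMC flagged: max split R-hat ",
            sprintf("%.3f", max(diag$rhat, na.rm = TRUE)),
            " >= 1.05; treat results with caution", call. = FALSE)
  }
  structure(list(draws = draws, samples = samples, index = index,
                 levels = vd$levels, variant = vd, spec = spec,
                 response = norm$response, raw_means = norm$raw_means,
                 shared_sd = norm$shared_sd, norm = norm,
                 diagnostics = diag, converged = diag$verdict),
            class = "heterogeneity_fit")
}

#' @export
print.heterogeneity_fit <- function(x, ...) {
  cat(sprintf("Heterogeneity fit (variant %s, response %s)\n",
              x$spec$variant, x$response))
  cat(sprintf("  %d matrices, %d samples, %d holders, %d spheres, %d observations\n",
              length(x$index$matrices), length(x$index$samples),
              length(x$index$holders), length(x$index$spheres),
              nrow(x$norm$data)))
  cat(sprintf("  %d draws | max Rhat %.3f | converged: %s\n",
              nrow(x$draws), max(x$diagnostics$rhat, na.rm = TRUE), x$converged))
  invisible(x)
}

level_param <- function(fit, level) {
  param <- fit$levels[level]
  abort_if(is.na(param), "unknown level '", level, "' for variant '",
           fit$spec$variant, "'; available: ",
           paste(names(fit$levels), collapse = ", "))
  unname(param)
}

level_draws <- function(fit, matrix, level) {
  m <- match(matrix, fit$index$matrices)
  abort_if(is.na(m), "unknown matrix '", matrix, "'")
  get_col(fit$draws, sprintf("%s[%d]", level_param(fit, level), m))
}

#' Posterior summary of a heterogeneity scale
#'
#' @param fit A `heterogeneity_fit`.
#' @param matrix Matrix label(s); default all fitted matrices.
#' @param level Which scatter scale to summarize (see [build_variant()] for
#'   the level names of each variant). Default is the headline
#'   sphere-within-holder heterogeneity.
#' @return Data frame (one row per matrix) with posterior mean, SD and
#'   5/25/50/75/95% quantiles; a per-matrix kernel `density` grid is attached
#'   as attribute `"density"`.
#' @export
heterogeneity_summary <- function(fit, matrix = NULL,
                                  level = "sphere_within_holder") {
  stopifnot(inherits(fit, "heterogeneity_fit"))
  matrix <- matrix %||% fit$index$matrices
  rows <- lapply(matrix, function(m) {
    d <- level_draws(fit, m, level)
    q <- stats::quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(matrix = m, level = level, mean = mean(d), sd = stats::sd(d),
               q5 = q[1], q25 = q[2], median = q[3], q75 = q[4], q95 = q[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dens <- lapply(matrix, function(m) {
    d <- level_draws(fit, m, level)
    if (stats::sd(d) == 0) return(NULL)
    stats::density(d, from = 0, n = 256)
  })
  names(dens) <- matrix
  attr(out, "density") <- dens
  out
}

#' Posterior probability that one matrix is more heterogeneous than another
#'
#' Monte-Carlo estimate of `P(scale_a > scale_b)` from draws paired by
#' iteration, both matrices having been fitted in the same run.
#'
#' @param fit A `heterogeneity_fit`.
#' @param matrix_a,matrix_b Matrix labels.
#' @param level Scatter scale to compare (default sphere-within-holder).
#' @return Probability in \[0, 1\].
#' @export
pairwise_probability <- function(fit, matrix_a, matrix_b,
                                 level = "sphere_within_holder") {
  a <- level_draws(fit, matrix_a, level)
  b <- level_draws(fit, matrix_b, level)
  abort_if(length(a) != length(b), "draw counts differ between matrices")
  mean(a > b)
}

# ---- MCMC diagnostics -------------------------------------------------------

split_rhat_one <- function(chains) {
  # chains: list of numeric vectors, one per chain; split each in half
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for MCMC draws
#'
#' Split-chain R-hat and effective sample size per monitored scalar, plus a
#' pass/fail verdict. Divergence counts are an HMC-specific diagnostic and
#' are reported as `NA` for the Gibbs sampler used here.
#'
#' @param x A coda `mcmc.list` (>= 2 chains required for R-hat) or a
#'   `heterogeneity_fit`/`calibration_fit`.
#' @param rhat_threshold Verdict threshold on the maximum R-hat
#'   (default 1.05).
#' @return List with `rhat` (named), `ess` (named), `divergences` (`NA`),
#'   `n_draws` and logical `verdict`.
#' @export
mcmc_diagnostics <- function(x, rhat_threshold = 1.05) {
  if (inherits(x, "heterogeneity_fit")) x <- x$samples
  if (inherits(x, "calibration_fit")) stop("use fit$diagnostics", call. = FALSE)
  stopifnot(coda::is.mcmc.list(x) || coda::is.mcmc(x))
  if (coda::is.mcmc(x)) x <- coda::mcmc.list(x)
  params <- colnames(x[[1]])
  single_chain <- length(x) < 2
  rhat <- vapply(params, function(p) {
    if (single_chain) return(NA_real_)
    split_rhat_one(lapply(x, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  ess <- tryCatch(coda::effectiveSize(x), error = function(e) {
    stats::setNames(rep(NA_real_, length(params)), params)
  })
  if (single_chain) {
    warning("single chain: R-hat unavailable, verdict based on ESS only",
            call. = FALSE)
  }
  verdict <- if (single_chain) all(is.finite(ess)) else {
    all(rhat < rhat_threshold, na.rm = TRUE)
  }
  list(rhat = rhat, ess = ess, divergences = NA_integer_,
       n_draws = length(x) * nrow(x[[1]]), verdict = verdict)
}
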