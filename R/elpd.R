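# Leave-one-sphere-out expected log pointwise predictive density. A "point"
# is one magnetic sphere (all its repeats jointly). The held-out sphere's
# mean is integrated out analytically — given its noise SD, the repeats are
# jointly Gaussian with a compound-symmetric covariance — so only the
# inverse-gamma noise SD (and any missing-ancestor innovations, which fold
# into the compound term) needs Monte-Carlo integration.

get_col <- function(draws, name) {
  if (!name %in% colnames(draws)) {
    # JAGS drops the index from length-1 monitored vectors
    bare <- sub("\\[1\\]$", "", name)
    abort_if(!bare %in% colnames(draws), "parameter ", name, " was not monitored")
    name <- bare
  }
  draws[, name]
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

row_log_mean_exp <- function(x) {
  m <- apply(x, 1, max)
  ok <- is.finite(m)
  out <- m
  out[ok] <- m[ok] + log(rowMeans(exp(x[ok, , drop = FALSE] - m[ok])))
  out
}

# Joint log density of R exchangeable repeats y given a Gaussian mean with
# conditional mean `mu`, between-repeat (shared) variance `s2` and
# within-repeat variance `sig2`: y ~ MVN(mu, s2*J + sig2*I).
comp_sym_logdens <- function(y, mu, s2, sig2) {
  R <- length(y)
  ss <- vapply(seq_along(mu), function(d) sum((y - mu[d])^2), numeric(1))
  s1 <- R * (mean(y) - mu)
  # mu, s2 recycle over draws; sig2 may be a draws x sims matrix
  denom <- sig2 + R * s2
  -0.5 * ((R - 1) * log(sig2) + log(denom) + R * log(2 * pi)) -
    0.5 * (ss / sig2 - (s2 * s1^2) / (sig2 * denom))
}

# Conditional mean of the held-out sphere's parent node plus any extra
# variance from ancestors absent in the training fit (their innovations are
# Gaussian and fold into the compound-symmetric term).
ancestor_state <- function(draws, variant_def, index_fit, sphere_info) {
  m <- sphere_info$matrix_idx
  v <- variant_def$variant
  zero <- numeric(nrow(draws))
  if (v == "single_level") {
    return(list(mu = get_col(draws, sprintf("mu_matrix[%d]", m)), var = zero))
  }
  if (v == "location_level") {
    li <- match(sphere_info$location_key, index_fit$locations)
    if (!is.na(li)) {
      return(list(mu = get_col(draws, sprintf("mu_location[%d]", li)), var = zero))
    }
    loc_var <- get_col(draws, sprintf("scale_location[%d]", m))^2
    hi <- match(sphere_info$holder_key, index_fit$holders)
    if (!is.na(hi)) {
      return(list(mu = get_col(draws, sprintf("mu_holder[%d]", hi)), var = loc_var))
    }
    si <- match(sphere_info$sample_key, index_fit$samples)
    hold_var <- get_col(draws, sprintf("scale_holder[%d]", m))^2
    if (!is.na(si)) {
      return(list(mu = get_col(draws, sprintf("mu_sample[%d]", si)),
                  var = loc_var + hold_var))
    }
    return(list(mu = get_col(draws, sprintf("mu_matrix[%d]", m)),
                var = loc_var + hold_var +
                  get_col(draws, sprintf("scale_sample[%d]", m))^2))
  }
  # primary
  hi <- match(sphere_info$holder_key, index_fit$holders)
  if (!is.na(hi)) {
    return(list(mu = get_col(draws, sprintf("mu_holder[%d]", hi)), var = zero))
  }
  si <- match(sphere_info$sample_key, index_fit$samples)
  hold_var <- get_col(draws, sprintf("scale_holder[%d]", m))^2
  if (!is.na(si)) {
    return(list(mu = get_col(draws, sprintf("mu_sample[%d]", si)), var = hold_var))
  }
  list(mu = get_col(draws, sprintf("mu_matrix[%d]", m)),
       var = hold_var + get_col(draws, sprintf("scale_sample[%d]", m))^2)
}

noise_shape_rate <- function(draws, variant_def, m) {
  shape <- get_col(draws, "sigma_mu")
  rate <- get_col(draws, sprintf("sigma_sigma[%d]", m))
  if (isTRUE(attr(variant_def, "noise_mean_sd"))) {
    sh <- 2 + (shape / rate)^2
    rate <- shape * (sh - 1)
    shape <- sh
  }
  list(shape = shape, rate = rate)
}

# Per-draw integrated log predictive density of a held-out sphere's repeats;
# returns an S-vector.
sphere_predictive_lp <- function(fit_draws, variant_def, index_fit,
                                 sphere_info, y_held, n_sim) {
  S <- nrow(fit_draws)
  m <- sphere_info$matrix_idx
  v <- variant_def$variant
  if (v == "pooled_no_shared_noise") {
    mu <- get_col(fit_draws, sprintf("mu_matrix[%d]", m))
    sdv <- get_col(fit_draws, sprintf("s_matrix[%d]", m))
    ll <- vapply(y_held, function(yy) stats::dnorm(yy, mu, sdv, log = TRUE),
                 numeric(S))
    return(rowSums(as.matrix(ll)))
  }
  nsr <- noise_shape_rate(fit_draws, variant_def, m)
  sig2 <- matrix(1 / stats::rgamma(S * n_sim, shape = rep(nsr$shape, n_sim),
                                   rate = rep(nsr$rate, n_sim)), S, n_sim)^2
  if (v == "pooled_baseline") {
    mu <- get_col(fit_draws, sprintf("mu_matrix[%d]", m))
    tot2 <- get_col(fit_draws, sprintf("s_matrix[%d]", m))^2 + sig2
    ss <- vapply(seq_len(S), function(d) sum((y_held - mu[d])^2), numeric(1))
    ll <- -0.5 * (length(y_held) * log(2 * pi * tot2) + ss / tot2)
    return(row_log_mean_exp(ll))
  }
  anc <- ancestor_state(fit_draws, variant_def, index_fit, sphere_info)
  s2 <- get_col(fit_draws, sprintf("scale_sphere[%d]", m))^2 + anc$var
  ll <- comp_sym_logdens(y_held, anc$mu, s2, sig2)
  row_log_mean_exp(ll)
}

sphere_table <- function(index) {
  data.frame(sphere_key = index$spheres,
             matrix_idx = index$sphere_matrix,
             holder_key = index$holders[index$sphere_holder],
             location_key = index$locations[index$sphere_location],
             sample_key = index$samples[index$holder_sample[index$sphere_holder]],
             stringsAsFactors = FALSE)
}

#' Leave-one-sphere-out expected log pointwise predictive density
#'
#' Cross-validates a heterogeneity model by holding out one magnetic sphere
#' (all its repeats) at a time. `method = "exact"` (default) refits the
#' model without the sphere and evaluates its log predictive density under
#' the refit posterior. `method = "importance"` is a fast path: one
#' full-data fit reweighted per sphere with truncated importance sampling
#' (weights capped at sqrt(S) times their mean); folds whose largest
#' normalized weight exceeds 0.2 are flagged. In both cases the held-out
#' sphere's mean is integrated analytically and its noise SD by simulation.
#'
#' @param norm A `normalized_obs`.
#' @param spec A [model_spec()].
#' @param method `"exact"` or `"importance"`.
#' @param n_sim Monte-Carlo draws per posterior draw for the noise-SD
#'   integral (default 40).
#' @param seed Seed for the predictive simulations (defaults to the MCMC
#'   seed).
#' @return List of class `elpd_loso`: `elpd`, `se`, `pointwise` (per-sphere
#'   log predictive densities), `method`, `flagged` (unconverged refit folds
#'   or heavy-weight folds) and `n_spheres`.
#' @export
elpd_loso <- function(norm, spec = model_spec(),
                      method = c("exact", "importance"), n_sim = 40,
                      seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(norm, "normalized_obs"))
  seed <- seed %||% spec$mcmc$seed
  vd <- build_variant(spec)
  attr(vd, "noise_mean_sd") <- spec$noise_parametrization == "mean_sd"
  index_full <- build_index(norm)
  abort_if(min(table(index_full$sphere_matrix)) < 2,
           "leave-one-sphere-out needs >= 2 spheres per matrix")
  d <- norm$data
  tkey <- paste(d$matrix, d$sample, d$holder, d$location, d$sphere, sep = "|")
  spheres <- sphere_table(index_full)
  flagged <- character(0)

  if (method == "importance") {
    fit <- suppressWarnings(fit_heterogeneity(norm, spec))
    if (!fit$converged) flagged <- c(flagged, "<full fit unconverged>")
    S <- nrow(fit$draws)
    pointwise <- with_seed(seed, vapply(seq_len(nrow(spheres)), function(ti) {
      info <- spheres[ti, ]
      y_held <- d$y[tkey == info$sphere_key]
      lp <- sphere_predictive_lp(fit$draws, vd, fit$index, info, y_held, n_sim)
      # truncated importance sampling: raw weights w = 1/p, cap mean(w)*sqrt(S)
      lw <- -lp
      lw_t <- pmin(lw, log_mean_exp(lw) + 0.5 * log(S))
      wmax_norm <- exp(max(lw_t) - (log_mean_exp(lw_t) + log(S)))
      if (wmax_norm > 0.2) flagged <<- c(flagged, info$sphere_key)
      log_mean_exp(lw_t + lp) - log_mean_exp(lw_t)
    }, numeric(1)))
  } else {
    pointwise <- vapply(seq_len(nrow(spheres)), function(ti) {
      info <- spheres[ti, ]
      keep <- tkey != info$sphere_key
      sub <- norm
      sub$data <- d[keep, , drop = FALSE]
      sub_spec <- spec
      sub_spec$mcmc$seed <- spec$mcmc$seed + ti
      refit <- suppressWarnings(fit_heterogeneity(sub, sub_spec))
      if (!refit$converged) flagged <<- c(flagged, info$sphere_key)
      info$matrix_idx <- match(d$matrix[!keep][1], refit$index$matrices)
      y_held <- d$y[!keep]
      lp <- with_seed(seed + ti,
        sphere_predictive_lp(refit$draws, vd, refit$index, info, y_held, n_sim))
      log_mean_exp(lp)
    }, numeric(1))
  }
  pw <- data.frame(sphere_key = spheres$sphere_key,
                   matrix = index_full$matrices[spheres$matrix_idx],
                   lpd = pointwise, stringsAsFactors = FALSE)
  structure(list(elpd = sum(pointwise),
                 se = sqrt(length(pointwise) * stats::var(pointwise)),
                 pointwise = pw, method = method, flagged = flagged,
                 n_spheres = nrow(spheres)),
            class = "elpd_loso")
}

#' @export
print.elpd_loso <- function(x, ...) {
  cat(sprintf("ELPD (leave-one-sphere-out, %s): %.2f +/- %.2f over %d spheres\n",
              x$method, x$elpd, x$se, x$n_spheres))
  if (length(x$flagged) > 0) {
    cat(" ", length(x$flagged), "flagged fold(s)\n")
  }
  invisible(x)
}
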