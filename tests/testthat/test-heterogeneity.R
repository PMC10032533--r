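test_that("normalization centers per matrix with one shared SD", {
  obs <- single_obs()[rep(1, 6), ]
  obs$sphere <- paste0("t", 1:6)
  obs$abs_shear_modulus_pa <- c(10, 20, 30, 40, 50, 60)
  nrm <- normalize_observations(obs)
  expect_equal(mean(nrm$data$y), 0)
  expect_equal(sd(nrm$data$y), 1)

  # two matrices, hand computation of the pooled centered SD
  obs$matrix <- rep(c("A", "B"), each = 3)
  nrm2 <- normalize_observations(obs)
  centered <- c(c(10, 20, 30) - 20, c(40, 50, 60) - 50)
  expect_equal(unname(nrm2$raw_means), c(20, 50), ignore_attr = TRUE)
  expect_equal(nrm2$shared_sd, sd(centered))
  expect_equal(nrm2$data$y, centered / sd(centered))

  # affine invariance: rescaling all raw data leaves y unchanged
  obs10 <- obs
  obs10$abs_shear_modulus_pa <- obs10$abs_shear_modulus_pa * 10
  expect_equal(normalize_observations(obs10)$data$y, nrm2$data$y,
               tolerance = 1e-12)
  # degenerate inputs
  expect_error(normalize_observations(obs[1, , drop = FALSE]), ">= 2")
  flat <- obs; flat$abs_shear_modulus_pa <- 5
  expect_error(normalize_observations(flat), "zero variance")
})

test_that("variant builder exposes the documented structures", {
  sp <- model_spec(mcmc = light_mcmc())
  vd <- build_variant(sp)
  expect_named(vd$levels, c("sample_within_matrix", "holder_within_sample",
                            "sphere_within_holder"))
  expect_match(vd$model_string, "mu_sphere\\[t\\] ~ dnorm\\(mu_holder")
  vd2 <- build_variant(model_spec(variant = "location_level", mcmc = light_mcmc()))
  expect_true("location_within_holder" %in% names(vd2$levels))
  expect_match(vd2$model_string, "mu_location")
  vd5 <- build_variant(model_spec(variant = "pooled_no_shared_noise",
                                  mcmc = light_mcmc()))
  expect_false(grepl("sigma_t", vd5$model_string))
  # the literal inverse-gamma noise reads (shape, scale) straight off
  expect_match(vd$model_string, "ig_shape_m\\[m\\] <- sigma_mu")
  vmean <- build_variant(model_spec(noise_parametrization = "mean_sd",
                                    mcmc = light_mcmc()))
  expect_match(vmean$model_string, "2 \\+ pow\\(sigma_mu / sigma_sigma")
})

test_that("fitting the primary variant uses exactly the built structure", {
  obs <- gen_visco_observations(hierarchy_design(2, 2, 2, 2, 2), seed = 9)
  nrm <- normalize_observations(obs)
  sp <- model_spec(mcmc = light_mcmc(seed = 2))
  fit <- suppressWarnings(fit_heterogeneity(nrm, sp))
  expect_identical(fit$variant$model_string, build_variant(sp)$model_string)
  expect_equal(nrow(fit$draws), sp$mcmc$chains * sp$mcmc$iter)
  # scale and noise draws are non-negative by construction
  sc <- fit$draws[, grep("^scale_|^sigma_", colnames(fit$draws))]
  expect_true(all(sc >= 0))
})

test_that("a zero sphere-level scatter shrinks toward zero", {
  tr <- generative_truth(matrices = "A", scale_sample = 0.6, scale_holder = 0.4,
                         scale_sphere = 0, noise_shape = 20, noise_scale = 0.5)
  obs <- gen_hierarchical_observations(hierarchy_design(3, 2, 3, 2, 2), tr,
                                       seed = 17)
  obs$diameter_um <- 30; obs$phase_deg <- 5
  nrm <- normalize_observations(obs, "abs_shear_modulus_pa")
  fit <- suppressWarnings(
    fit_heterogeneity(nrm, model_spec(mcmc = light_mcmc(seed = 6, warmup = 600,
                                                        iter = 600))))
  q90 <- quantile(level_draws_for_test(fit, "A", "sphere_within_holder"), 0.9)
  expect_lt(unname(q90), 0.15)
})

test_that("summaries and pairwise probabilities reduce to their definitions", {
  set.seed(123)
  n <- 20000
  fit <- fake_het_fit(list("scale_sphere[1]" = rnorm(n, 1.0, 0.1),
                           "scale_sphere[2]" = rnorm(n, 0.5, 0.1)))
  s <- heterogeneity_summary(fit, "A")
  d <- fit$draws[, "scale_sphere[1]"]
  expect_equal(s$mean, mean(d))
  expect_equal(s$sd, sd(d))
  expect_equal(s$median, unname(quantile(d, 0.5)))
  # closed-form normal comparison: P(a > b) = Phi(0.5 / (0.1*sqrt(2)))
  p <- pairwise_probability(fit, "A", "B")
  expect_equal(p, pnorm(0.5 / (0.1 * sqrt(2))), tolerance = 0.005)
  # identically distributed draws -> 0.5; strictly ordered draws -> 1
  fit2 <- fake_het_fit(list("scale_sphere[1]" = rnorm(n),
                            "scale_sphere[2]" = rnorm(n)))
  expect_equal(pairwise_probability(fit2, "A", "B"), 0.5, tolerance = 0.02)
  fit3 <- fake_het_fit(list("scale_sphere[1]" = 5 + abs(rnorm(n)),
                            "scale_sphere[2]" = abs(rnorm(n)) / 2))
  expect_equal(pairwise_probability(fit3, "A", "B"), 1.0)
  # constant draws summarize to (c, 0)
  fitc <- fake_het_fit(list("scale_sphere[1]" = rep(0.7, 100),
                            "scale_sphere[2]" = rep(0.1, 100)))
  sc <- heterogeneity_summary(fitc, "A")
  expect_equal(sc$mean, 0.7)
  expect_equal(sc$sd, 0)
  expect_error(heterogeneity_summary(fit, "A", level = "nope"), "unknown level")
  expect_error(pairwise_probability(fit, "A", "C"), "unknown matrix")
})

test_that("adding identical-valued spheres never inflates sphere-level scatter", {
  obs <- gen_visco_observations(hierarchy_design(2, 2, 2, 2, 2), seed = 23)
  nrm <- normalize_observations(obs)
  base <- suppressWarnings(fit_heterogeneity(nrm, model_spec(mcmc = light_mcmc(seed = 3))))
  # append, within each holder, two spheres whose repeats sit exactly at the
  # holder mean: direct evidence of low within-holder scatter
  d <- nrm$data
  hkey <- paste(d$matrix, d$sample, d$holder)
  extra <- do.call(rbind, lapply(split(d, hkey), function(g) {
    out <- g[rep(1, 4), ]
    out$location <- "lx"
    out$sphere <- rep(c("tx1", "tx2"), each = 2)
    out$`repeat` <- rep(c("r1", "r2"), 2)
    out$y <- mean(g$y)
    out
  }))
  aug <- nrm
  aug$data <- rbind(d, extra)
  augfit <- suppressWarnings(fit_heterogeneity(aug, model_spec(mcmc = light_mcmc(seed = 3))))
  m_base <- mean(level_draws_for_test(base, "matrix1", "sphere_within_holder"))
  m_aug <- mean(level_draws_for_test(augfit, "matrix1", "sphere_within_holder"))
  expect_lt(m_aug, m_base + 0.05)
})

test_that("degenerate designs are permitted but flagged", {
  obs <- gen_visco_observations(hierarchy_design(2, 1, 1, 1, 2), seed = 2)
  nrm <- normalize_observations(obs)
  w <- capture_warnings(
    fit_heterogeneity(nrm, model_spec(mcmc = light_mcmc(seed = 1, warmup = 200,
                                                        iter = 200))))
  expect_true(any(grepl("degenerate design", w)))
})

test_that("split R-hat flags constructed convergence failures", {
  set.seed(9)
  good <- coda::mcmc.list(coda::mcmc(cbind(theta = rnorm(500))),
                          coda::mcmc(cbind(theta = rnorm(500))))
  bad <- coda::mcmc.list(coda::mcmc(cbind(theta = rnorm(500, 0))),
                         coda::mcmc(cbind(theta = rnorm(500, 5))))
  dg <- mcmc_diagnostics(good)
  db <- mcmc_diagnostics(bad)
  expect_lt(dg$rhat[["theta"]], 1.01)
  expect_true(dg$verdict)
  expect_gt(db$rhat[["theta"]], 1.5)
  expect_false(db$verdict)
  # ESS can never exceed the total number of draws (coda caps at the total)
  expect_lte(dg$ess[["theta"]], 1001)
  expect_true(is.na(dg$divergences))
  expect_warning(ds <- mcmc_diagnostics(coda::mcmc.list(good[[1]])), "single chain")
  expect_true(is.na(ds$rhat[["theta"]]))
})

test_that("prior-predictive simulation matches the generator distributionally", {
  des <- hierarchy_design(2, 2, 2, 1, 1)
  sp <- model_spec(mcmc = mcmc_config(chains = 1, warmup = 200, iter = 500,
                                      seed = 31, thin = 10))
  vd <- build_variant(sp)
  idx_obs <- suppressWarnings(
    gen_hierarchical_observations(des, generative_truth(), seed = 1))
  idx_obs$diameter_um <- 30; idx_obs$phase_deg <- 5
  nrm <- normalize_observations(idx_obs, "abs_shear_modulus_pa")
  index <- magrheo:::build_index(nrm)
  data <- magrheo:::jags_data_for(vd, index, nrm$data$y)

  # (a) level-effect chain: sphere means under free level hyperpriors (the
  # noise hypers are clamped to safe values; they do not enter mu_sphere)
  prior_data <- data; prior_data$y <- NULL
  prior_data$sigma_mu <- 3; prior_data$sigma_sigma <- 0.2
  jags_y <- suppressWarnings(
    magrheo:::run_jags(vd$model_string, prior_data, c("mu_sphere", "y"), sp$mcmc))
  mu1_jags <- as.matrix(jags_y)[, "mu_sphere[1]"]
  mu1_gen <- vapply(1:500, function(i) {
    tr <- magrheo:::with_seed(1000 + i, generative_truth(
      matrices = "A", mu_matrix = rnorm(1),
      scale_sample = abs(rnorm(1)), scale_holder = abs(rnorm(1)),
      scale_sphere = abs(rnorm(1)),
      noise_shape = 3, noise_scale = 0.2, raw_mean = 0, raw_sd = 1))
    suppressWarnings(
      gen_hierarchical_observations(des, tr, seed = 2000 + i))$mu_sphere[1]
  }, numeric(1))
  expect_gt(ks.test(mu1_jags, mu1_gen)$p.value, 0.01)

  # (b) observation chain with the hyperparameters clamped to the default
  # generative truth: full y marginal including the inverse-gamma noise
  clamp <- data
  clamp$y <- NULL
  clamp$mu_matrix <- 0
  clamp$scale_sample <- 0.3; clamp$scale_holder <- 0.2; clamp$scale_sphere <- 0.8
  clamp$sigma_mu <- 3; clamp$sigma_sigma <- 0.2
  jags_y2 <- suppressWarnings(
    magrheo:::run_jags(vd$model_string, clamp, "y", sp$mcmc))
  y1_jags <- as.matrix(jags_y2)[, "y[1]"]
  y1_gen <- vapply(1:500, function(i) {
    suppressWarnings(
      gen_hierarchical_observations(des, generative_truth(raw_mean = 0, raw_sd = 1),
                                    seed = 3000 + i))$y_norm[1]
  }, numeric(1))
  expect_gt(ks.test(y1_jags, y1_gen)$p.value, 0.01)
})
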