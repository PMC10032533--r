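# Shared fixtures: small, fast MCMC settings and canonical simulation inputs.

light_mcmc <- function(seed = 1, chains = 2, warmup = 400, iter = 400) {
  mcmc_config(chains = chains, warmup = warmup, iter = iter, seed = seed)
}

oil <- function(mu = 30) fluid_properties(dynamic_viscosity_pa_s = mu)

# Hand-built observation table: one sphere, known |G| and phase.
single_obs <- function(g_pa = 129.5, phase_deg = 5.46, diameter_um = 30) {
  data.frame(matrix = "agarose", sample = "s1", holder = "h1", location = "l1",
             sphere = "t1", `repeat` = "r1", diameter_um = diameter_um,
             abs_shear_modulus_pa = g_pa, phase_deg = phase_deg,
             check.names = FALSE, stringsAsFactors = FALSE)
}

obs_cols_for_test <- function() {
  c("matrix", "sample", "holder", "location", "sphere", "repeat",
    "diameter_um", "abs_shear_modulus_pa", "phase_deg")
}

level_draws_for_test <- function(fit, m, level) {
  magrheo:::level_draws(fit, m, level)
}

# A minimal fake heterogeneity fit wrapping externally supplied draws, for
# testing summary/pairwise arithmetic independently of the sampler.
fake_het_fit <- function(draws_list) {
  draws <- do.call(cbind, draws_list)
  colnames(draws) <- names(draws_list)
  structure(list(draws = draws,
                 index = list(matrices = c("A", "B")),
                 levels = c(sphere_within_holder = "scale_sphere"),
                 spec = list(variant = "primary")),
            class = "heterogeneity_fit")
}
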