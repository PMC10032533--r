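#' Drive-current configuration
#'
#' Describes the oscillatory force drive: the two electromagnet coils are fed
#' a shared offset current superposed with a sinusoidal gradient current of
#' amplitude `i_grad_amp` at frequency `frequency_hz`. Only the waveform
#' parameters matter for analysis; hardware control is out of scope.
#'
#' @param frequency_hz Drive frequency f in Hz (default 0.05).
#' @param i_grad_amp Gradient-current amplitude in A (default 1.25).
#' @param i_offset Offset current in A (default 0.75).
#' @return An object of class `drive_config`.
#' @export
drive_config <- function(frequency_hz = 0.05, i_grad_amp = 1.25, i_offset = 0.75) {
  check_positive(frequency_hz, "frequency_hz")
  check_positive(i_grad_amp, "i_grad_amp", strict = FALSE)
  check_positive(i_offset, "i_offset", strict = FALSE)
  structure(list(frequency_hz = frequency_hz,
                 i_grad_amp = i_grad_amp,
                 i_offset = i_offset),
            class = "drive_config")
}

#' Newtonian fluid properties for calibration
#'
#' @param dynamic_viscosity_pa_s Dynamic viscosity mu in Pa·s. The default,
#'   30 Pa·s, corresponds to a nominal 30 000 cSt silicone oil under a
#'   density assumption of ~1 g/mL; override when the oil batch is
#'   characterized in dynamic units.
#' @param temperature_note Free-text note on the measurement temperature.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(dynamic_viscosity_pa_s = 30,
                             temperature_note = "room temperature") {
  check_positive(dynamic_viscosity_pa_s, "dynamic_viscosity_pa_s")
  structure(list(dynamic_viscosity_pa_s = dynamic_viscosity_pa_s,
                 temperature_note = temperature_note),
            class = "fluid_properties")
}

#' MCMC sampler configuration
#'
#' Settings handed to the JAGS sampler. `warmup` iterations are used for
#' adaptation and burn-in and discarded; `iter` iterations per chain are kept.
#'
#' @param chains Number of chains (>= 2 required for split R-hat).
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param iter Kept iterations per chain.
#' @param seed Integer seed; chain c uses `seed + c` for its RNG stream.
#' @param thin Thinning interval.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iter = 1000, seed = 1, thin = 1) {
  check_positive(chains, "chains")
  check_positive(warmup, "warmup")
  check_positive(iter, "iter")
  check_positive(thin, "thin")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 thin = as.integer(thin)),
            class = "mcmc_config")
}

#' Nested experimental design for one matrix type
#'
#' The study design nests, within each matrix type: samples, sample holders
#' per sample, imaged locations per holder, magnetic spheres per location and
#' repeated measurements per sphere. Defaults mirror the design used for the
#' heterogeneity experiments: 3 samples x 2 holders x 3-5 locations x 1-3
#' spheres x 2 repeats.
#'
#' @param n_samples Samples per matrix type (S).
#' @param n_holders Sample holders per sample (H).
#' @param n_locations Imaged locations per holder (L); scalar or range
#'   `c(min, max)` sampled uniformly per holder.
#' @param spheres_per_location Spheres per location; scalar or range
#'   `c(min, max)` sampled uniformly per location.
#' @param n_repeats Repeated measurements per sphere (R).
#' @return An object of class `hierarchy_design`.
#' @export
hierarchy_design <- function(n_samples = 3, n_holders = 2, n_locations = c(3, 5),
                             spheres_per_location = c(1, 3), n_repeats = 2) {
  for (v in list(n_samples, n_holders, n_locations, spheres_per_location, n_repeats)) {
    abort_if(any(!is.finite(v) | v < 1), "design counts must all be >= 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_holders = as.integer(n_holders),
                 n_locations = as.integer(n_locations),
                 spheres_per_location = as.integer(spheres_per_location),
                 n_repeats = as.integer(n_repeats)),
            class = "hierarchy_design")
}

#' Ground truth for the hierarchical observation generator
#'
#' Parameters of the generative chain on the normalized (z) scale, one value
#' per matrix type, plus the raw-scale constants used to de-normalize. The
#' scales are named by the level whose children they scatter:
#' `scale_sample` scatters sample means within a matrix, `scale_holder`
#' scatters holder means within a sample and `scale_sphere` scatters sphere
#' means within a holder (the headline heterogeneity). Per-sphere measurement
#' noise SDs are drawn from InverseGamma(`noise_shape`, `noise_scale_m`).
#'
#' @param matrices Character vector of matrix-type labels.
#' @param mu_matrix Normalized-scale matrix means (recycled).
#' @param scale_sample,scale_holder,scale_sphere Level scatter scales
#'   (non-negative, recycled).
#' @param noise_shape Shared shape of the per-sphere noise distribution
#'   (the pooled mean-noise hyperparameter).
#' @param noise_scale Matrix-specific scale of the noise distribution
#'   (recycled).
#' @param raw_mean Raw-scale mean per matrix used to de-normalize (recycled).
#' @param raw_sd Single raw-scale SD shared by all matrices.
#' @return An object of class `generative_truth`.
#' @export
generative_truth <- function(matrices = "matrix1",
                             mu_matrix = 0,
                             scale_sample = 0.3,
                             scale_holder = 0.2,
                             scale_sphere = 0.8,
                             noise_shape = 3,
                             noise_scale = 0.2,
                             raw_mean = 100,
                             raw_sd = 50) {
  m <- length(matrices)
  abort_if(m < 1 || anyNA(matrices) || any(!nzchar(matrices)),
           "`matrices` must be non-empty labels")
  rec <- function(x) rep_len(x, m)
  for (nm in c("scale_sample", "scale_holder", "scale_sphere", "noise_scale")) {
    check_positive(get(nm), nm, strict = FALSE)
  }
  check_positive(noise_shape, "noise_shape")
  check_positive(raw_sd, "raw_sd")
  structure(list(matrices = as.character(matrices),
                 mu_matrix = rec(mu_matrix),
                 scale_sample = rec(scale_sample),
                 scale_holder = rec(scale_holder),
                 scale_sphere = rec(scale_sphere),
                 noise_shape = noise_shape,
                 noise_scale = rec(noise_scale),
                 raw_mean = rec(raw_mean),
                 raw_sd = raw_sd),
            class = "generative_truth")
}
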