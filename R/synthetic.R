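# Synthetic-data generators. These emulate the statistical structure of the
# real experiment — sinusoidal displacement at the drive frequency with phase
# lag, additive tracking noise and drift, sphere-size dispersion, and the
# nested sample/holder/location/sphere/repeat hierarchy — with ground truth
# recorded alongside every dataset.

track_columns <- c("matrix", "sample", "holder", "location", "sphere",
                   "repeat", "time_s", "displacement_m", "diameter_um")

obs_columns <- c("matrix", "sample", "holder", "location", "sphere",
                 "repeat", "diameter_um", "abs_shear_modulus_pa", "phase_deg")

# Truncated-normal diameters: truncation at +/- 3 SD and at zero so sizes are
# always physical.
draw_diameters <- function(n, mean_m, sd_m) {
  check_positive(mean_m, "diameter mean")
  check_positive(sd_m, "diameter sd", strict = FALSE)
  if (sd_m == 0) return(rep(mean_m, n))
  lo <- max(0, mean_m - 3 * sd_m)
  hi <- mean_m + 3 * sd_m
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    d <- stats::rnorm(length(need), mean_m, sd_m)
    ok <- d > lo & d < hi
    out[need[ok]] <- d[ok]
    need <- need[!ok]
  }
  out
}

sample_time_grid <- function(duration_s, sample_rate_hz, frequency_hz) {
  check_positive(duration_s, "duration_s")
  check_positive(sample_rate_hz, "sample_rate_hz")
  abort_if(duration_s < 1 / frequency_hz,
           "duration_s must cover at least one full drive period (",
           signif(1 / frequency_hz, 4), " s)")
  seq(0, duration_s, by = 1 / sample_rate_hz)
}

#' Generate calibration tracks of magnetic spheres in a viscous fluid
#'
#' Simulates the calibration experiment: magnetic spheres suspended in a
#' Newtonian fluid of known viscosity are driven by a sinusoidal volumetric
#' force. In the viscous (Stokes-drag) limit the noiseless displacement is
#' `p(t) = p_hat * sin(2*pi*f*t - 90 deg)` with amplitude
#' `p_hat = F_vol * V / (3*pi*mu*D * 2*pi*f)`, i.e. the velocity amplitude
#' satisfies `F_vol = 18*mu*v_hat/D^2`. Additive white tracking noise is then
#' applied.
#'
#' @param f_volumetric True volumetric force constant (N/m^3).
#' @param fluid A [fluid_properties()] object.
#' @param n_spheres Number of spheres.
#' @param diameter_mean_um,diameter_sd_um Sphere-diameter distribution
#'   (truncated normal), in micrometres.
#' @param drive A [drive_config()] object.
#' @param noise_sd_m SD of additive white tracking noise on displacement (m).
#' @param duration_s,sample_rate_hz Track length and sampling rate. Defaults
#'   cover one full period of the 0.05 Hz drive at 25 Hz sampling.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `calibration_sim` with elements `tracks` (tidy
#'   track data frame), `spheres` (per-sphere diameters) and `truth`
#'   (generator parameters, including the seed).
#' @export
gen_calibration_tracks <- function(f_volumetric, fluid, n_spheres = 50,
                                   diameter_mean_um = 30, diameter_sd_um = 3,
                                   drive = drive_config(), noise_sd_m = 0,
                                   duration_s = 20, sample_rate_hz = 25,
                                   seed = 1) {
  check_positive(f_volumetric, "f_volumetric")
  stopifnot(inherits(fluid, "fluid_properties"), inherits(drive, "drive_config"))
  check_positive(n_spheres, "n_spheres")
  check_positive(noise_sd_m, "noise_sd_m", strict = FALSE)
  f <- drive$frequency_hz
  mu <- fluid$dynamic_viscosity_pa_s
  times <- sample_time_grid(duration_s, sample_rate_hz, f)

  with_seed(seed, {
    diam_m <- draw_diameters(n_spheres, diameter_mean_um * 1e-6,
                             diameter_sd_um * 1e-6)
    ids <- sprintf("cal%03d", seq_len(n_spheres))
    tracks <- do.call(rbind, lapply(seq_len(n_spheres), function(i) {
      # viscous limit: velocity in phase with the force => displacement lags 90 deg
      v_hat <- f_volumetric * diam_m[i]^2 / (18 * mu)
      p_hat <- v_hat / (2 * pi * f)
      disp <- p_hat * sin(2 * pi * f * times - pi / 2)
      if (noise_sd_m > 0) disp <- disp + stats::rnorm(length(times), 0, noise_sd_m)
      data.frame(matrix = "calibration", sample = "cal", holder = "cal",
                 location = "cal", sphere = ids[i], `repeat` = "r1",
                 time_s = times, displacement_m = disp,
                 diameter_um = diam_m[i] * 1e6,
                 check.names = FALSE, stringsAsFactors = FALSE)
    }))
    spheres <- data.frame(sphere = ids, diameter_um = diam_m * 1e6,
                          stringsAsFactors = FALSE)
    truth <- list(f_volumetric = f_volumetric,
                  dynamic_viscosity_pa_s = mu,
                  diameter_mean_um = diameter_mean_um,
                  diameter_sd_um = diameter_sd_um,
                  noise_sd_m = noise_sd_m, drive = drive, seed = seed)
    structure(list(tracks = tracks, spheres = spheres, truth = truth),
              class = "calibration_sim")
  })
}

# Forward-sample the nested generative chain for one response on the
# normalized scale, then de-normalize. Shared by the public generators.
# Vectorized level by level; RNG order is part of the determinism contract.
sample_hierarchy <- function(design, truth) {
  draw_count <- function(range, n) {
    if (length(range) > 1) sample(range[1]:range[2], n, replace = TRUE)
    else rep(range, n)
  }
  per_matrix <- lapply(seq_along(truth$matrices), function(mi) {
    m <- truth$matrices[mi]
    S <- design$n_samples; H <- design$n_holders; R <- design$n_repeats
    mu_sample <- truth$mu_matrix[mi] + truth$scale_sample[mi] * stats::rnorm(S)
    holder_sample <- rep(seq_len(S), each = H)
    mu_holder <- mu_sample[holder_sample] +
      truth$scale_holder[mi] * stats::rnorm(S * H)
    nl <- draw_count(design$n_locations, S * H)
    loc_holder <- rep(seq_len(S * H), nl)
    loc_within <- sequence(nl)
    nt <- draw_count(design$spheres_per_location, length(loc_holder))
    sph_loc <- rep(seq_along(loc_holder), nt)
    sph_within <- sequence(nt)
    NT <- length(sph_loc)
    mu_sphere <- mu_holder[loc_holder[sph_loc]] +
      truth$scale_sphere[mi] * stats::rnorm(NT)
    sigma_t <- rinvgamma(NT, truth$noise_shape, truth$noise_scale[mi])
    obs_sphere <- rep(seq_len(NT), each = R)
    y <- stats::rnorm(NT * R, mu_sphere[obs_sphere], sigma_t[obs_sphere])
    hh <- loc_holder[sph_loc[obs_sphere]]
    data.frame(
      matrix = m,
      sample = sprintf("s%d", holder_sample[hh]),
      holder = sprintf("h%d", ((hh - 1) %% H) + 1),
      location = sprintf("l%d", loc_within[sph_loc[obs_sphere]]),
      sphere = sprintf("t%d_%d", loc_within[sph_loc[obs_sphere]],
                       sph_within[obs_sphere]),
      `repeat` = sprintf("r%d", rep(seq_len(R), NT)),
      y_norm = y,
      mu_sphere = mu_sphere[obs_sphere],
      sigma_t = sigma_t[obs_sphere],
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_matrix)
  out$y_raw <- out$y_norm * truth$raw_sd +
    truth$raw_mean[match(out$matrix, truth$matrices)]
  rownames(out) <- NULL
  out
}

#' Generate hierarchical observations with known ground truth
#'
#' Forward-samples the nested generative chain used by the heterogeneity
#' model: standard-normal level innovations are scaled by the level scatter
#' scales and accumulated matrix -> sample -> holder -> sphere; each sphere
#' receives an InverseGamma-distributed measurement-noise SD and
#' conditionally i.i.d. Gaussian repeats. Values are generated on the
#' normalized scale and de-normalized with the raw-scale constants recorded
#' in `truth`.
#'
#' @param design A [hierarchy_design()] object.
#' @param truth A [generative_truth()] object.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param response_name Name for the raw-scale response column.
#' @return A data frame with one row per repeat (hierarchy labels, latent
#'   `mu_sphere` and `sigma_t`, normalized `y_norm` and the raw-scale
#'   response), with the `generative_truth` attached as attribute `"truth"`.
#' @export
gen_hierarchical_observations <- function(design = hierarchy_design(),
                                          truth = generative_truth(),
                                          seed = 1,
                                          response_name = "abs_shear_modulus_pa") {
  stopifnot(inherits(design, "hierarchy_design"),
            inherits(truth, "generative_truth"))
  if (design$n_repeats < 2) {
    warning("fewer than 2 repeats per sphere: per-sphere noise is only ",
            "weakly identified downstream", call. = FALSE)
  }
  out <- with_seed(seed, sample_hierarchy(design, truth))
  names(out)[names(out) == "y_raw"] <- response_name
  truth$seed <- seed
  attr(out, "truth") <- truth
  out
}

#' Generate a full synthetic viscoelastic observation table
#'
#' Convenience wrapper drawing absolute shear modulus and phase angle from
#' two independent generative chains (same hierarchy labels), plus sphere
#' diameters, producing a table in the shape the rheology stage outputs.
#'
#' @param design A [hierarchy_design()] object.
#' @param truth_g Ground truth for the shear-modulus chain (raw scale Pa).
#' @param truth_phi Ground truth for the phase-angle chain (raw scale deg).
#' @param diameter_mean_um,diameter_sd_um Per-sphere diameter distribution.
#' @param seed Integer seed.
#' @return A `ViscoObservation`-style data frame (one row per repeat) with
#'   attribute `"truth"` holding both chains' truths.
#' @export
gen_visco_observations <- function(design = hierarchy_design(),
                                   truth_g = generative_truth(raw_mean = 100, raw_sd = 20),
                                   truth_phi = generative_truth(raw_mean = 8, raw_sd = 3),
                                   diameter_mean_um = 30, diameter_sd_um = 3,
                                   seed = 1) {
  g <- gen_hierarchical_observations(design, truth_g, seed = seed,
                                     response_name = "abs_shear_modulus_pa")
  # fixed hierarchy: regenerate labels jointly by reusing g's rows and drawing
  # phase on the same structure
  phi <- with_seed(seed + 1, {
    key <- paste(g$matrix, g$sample, g$holder, g$location, g$sphere, sep = "|")
    sphere_keys <- unique(key)
    mi <- match(g$matrix, truth_phi$matrices)
    abort_if(anyNA(mi), "truth_phi must cover every matrix label in truth_g")
    # walk the chain per matrix/sample/holder on g's realized structure
    mu_sample <- new.env(); mu_holder <- new.env()
    sphere_mu <- numeric(length(sphere_keys)); sphere_sd <- numeric(length(sphere_keys))
    names(sphere_mu) <- sphere_keys; names(sphere_sd) <- sphere_keys
    for (sk in sphere_keys) {
      parts <- strsplit(sk, "|", fixed = TRUE)[[1]]
      m <- parts[1]; mj <- match(m, truth_phi$matrices)
      skey <- paste(parts[1:2], collapse = "|")
      hkey <- paste(parts[1:3], collapse = "|")
      if (is.null(mu_sample[[skey]])) {
        mu_sample[[skey]] <- truth_phi$mu_matrix[mj] +
          truth_phi$scale_sample[mj] * stats::rnorm(1)
      }
      if (is.null(mu_holder[[hkey]])) {
        mu_holder[[hkey]] <- mu_sample[[skey]] +
          truth_phi$scale_holder[mj] * stats::rnorm(1)
      }
      sphere_mu[sk] <- mu_holder[[hkey]] + truth_phi$scale_sphere[mj] * stats::rnorm(1)
      sphere_sd[sk] <- rinvgamma(1, truth_phi$noise_shape, truth_phi$noise_scale[mj])
    }
    y_norm <- stats::rnorm(nrow(g), sphere_mu[key], sphere_sd[key])
    y_norm * truth_phi$raw_sd + truth_phi$raw_mean[match(g$matrix, truth_phi$matrices)]
  })
  diam <- with_seed(seed + 2, {
    key <- paste(g$matrix, g$sample, g$holder, g$location, g$sphere, sep = "|")
    uk <- unique(key)
    d <- draw_diameters(length(uk), diameter_mean_um * 1e-6, diameter_sd_um * 1e-6)
    names(d) <- uk
    d[key] * 1e6
  })
  out <- data.frame(g[c("matrix", "sample", "holder", "location", "sphere", "repeat")],
                    diameter_um = unname(diam),
                    abs_shear_modulus_pa = g$abs_shear_modulus_pa,
                    phase_deg = phi,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(abs_shear_modulus_pa = attr(g, "truth"),
                             phase_deg = truth_phi, seed = seed)
  out
}

#' Generate matrix-measurement tracks from an observation table
#'
#' Inverts the rheology relation: for each observation the noiseless
#' displacement amplitude is `p_hat = F_vol * D^2 / (18 * |G|)` and the track
#' is `p_hat * sin(2*pi*f*t - phi) + drift_slope * t + noise`. A round trip
#' through the signal and rheology stages recovers `(|G|, phi)` exactly at
#' zero noise and drift.
#'
#' @param observations Observation table with hierarchy labels,
#'   `diameter_um`, `abs_shear_modulus_pa` (> 0) and `phase_deg` columns.
#' @param f_volumetric Calibrated volumetric force constant (N/m^3).
#' @param drive A [drive_config()] object.
#' @param noise_sd_m Additive white tracking-noise SD (m).
#' @param drift_slope_m_s Linear drift slope (m/s).
#' @param duration_s,sample_rate_hz Track length and sampling rate.
#' @param seed Integer seed.
#' @return A tidy track data frame (one row per frame).
#' @export
gen_matrix_tracks <- function(observations, f_volumetric,
                              drive = drive_config(), noise_sd_m = 0,
                              drift_slope_m_s = 0, duration_s = 20,
                              sample_rate_hz = 25, seed = 1) {
  check_columns(observations, obs_columns, "observations")
  check_positive(f_volumetric, "f_volumetric")
  abort_if(any(!is.finite(observations$abs_shear_modulus_pa) |
                 observations$abs_shear_modulus_pa <= 0),
           "all abs_shear_modulus_pa values must be > 0")
  check_positive(observations$diameter_um, "diameter_um")
  f <- drive$frequency_hz
  times <- sample_time_grid(duration_s, sample_rate_hz, f)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(observations)), function(i) {
      row <- observations[i, ]
      d_m <- row$diameter_um * 1e-6
      p_hat <- f_volumetric * d_m^2 / (18 * row$abs_shear_modulus_pa)
      phi <- row$phase_deg * pi / 180
      disp <- p_hat * sin(2 * pi * f * times - phi) + drift_slope_m_s * times
      if (noise_sd_m > 0) disp <- disp + stats::rnorm(length(times), 0, noise_sd_m)
      data.frame(matrix = row$matrix, sample = row$sample, holder = row$holder,
                 location = row$location, sphere = row$sphere,
                 `repeat` = row$`repeat`, time_s = times, displacement_m = disp,
                 diameter_um = row$diameter_um,
                 check.names = FALSE, stringsAsFactors = FALSE)
    }))
    out
  })
}
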