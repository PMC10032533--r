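test_that("calibration generator inverts Stokes drag and is deterministic", {
  # noiseless tracks: fitted phase is exactly 90 deg (viscous limit) and the
  # velocity amplitude satisfies F_vol = 18*mu*v_hat/D^2 to round-off
  sim <- gen_calibration_tracks(2.59e5, oil(30), n_spheres = 4,
                                diameter_mean_um = 30, diameter_sd_um = 0,
                                noise_sd_m = 0, seed = 7)
  fits <- fit_tracks(sim$tracks)
  expect_equal(fits$phase_deg, rep(90, 4), tolerance = 1e-8)
  v_hat <- velocity_amplitude(fits$amplitude_m, drive_config())
  # hand evaluation: 2.59e5 * (30e-6)^2 / (18*30) = 4.31667e-7 m/s
  expect_equal(v_hat, rep(2.59e5 * 9e-10 / 540, 4), tolerance = 1e-10)
  f_back <- per_sphere_force_constant(fits$diameter_um * 1e-6 / 2, v_hat, oil(30))
  expect_equal(f_back, rep(2.59e5, 4), tolerance = 1e-10)

  sim2 <- gen_calibration_tracks(2.59e5, oil(30), n_spheres = 4,
                                 diameter_mean_um = 30, diameter_sd_um = 0,
                                 noise_sd_m = 0, seed = 7)
  expect_identical(sim$tracks, sim2$tracks)
  sim3 <- gen_calibration_tracks(2.59e5, oil(30), n_spheres = 4,
                                 diameter_mean_um = 30, diameter_sd_um = 3,
                                 noise_sd_m = 1e-9, seed = 8)
  expect_false(identical(sim$tracks$displacement_m, sim3$tracks$displacement_m))
})

test_that("calibration generator rejects unphysical inputs", {
  expect_error(fluid_properties(-1), "positive")
  expect_error(gen_calibration_tracks(2.59e5, oil(), duration_s = 5),
               "full drive period")
  expect_error(gen_calibration_tracks(-1, oil()), "positive")
})

test_that("hierarchical generator degenerates to the matrix mean and is deterministic", {
  # all scatter scales zero and noise concentrated near zero: every
  # observation equals the de-normalized matrix mean
  tr <- generative_truth(matrices = "A", mu_matrix = 0.5,
                         scale_sample = 0, scale_holder = 0, scale_sphere = 0,
                         noise_shape = 1e7, noise_scale = 1e-4,
                         raw_mean = 100, raw_sd = 50)
  obs <- gen_hierarchical_observations(hierarchy_design(2, 2, 2, 2, 2), tr, seed = 3)
  expect_equal(obs$abs_shear_modulus_pa, rep(100 + 0.5 * 50, nrow(obs)),
               tolerance = 1e-6)

  a <- gen_hierarchical_observations(seed = 11)
  b <- gen_hierarchical_observations(seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$y_norm,
                         gen_hierarchical_observations(seed = 12)$y_norm))
})

test_that("sphere-mean variance matches the law of total variance", {
  # independent chains (one holder/location/sphere per sample): the variance
  # of sphere means is the sum of the squared level scales
  tr <- generative_truth(matrices = "A", scale_sample = 0.3, scale_holder = 0.2,
                         scale_sphere = 0.8, noise_shape = 1e6, noise_scale = 1e-4)
  des <- hierarchy_design(n_samples = 4000, n_holders = 1, n_locations = 1,
                          spheres_per_location = 1, n_repeats = 1)
  obs <- suppressWarnings(gen_hierarchical_observations(des, tr, seed = 42))
  truth_var <- 0.3^2 + 0.2^2 + 0.8^2
  mc_se <- truth_var * sqrt(2 / (nrow(obs) - 1))
  expect_lt(abs(var(obs$mu_sphere) - truth_var), 3 * mc_se)
})

test_that("matrix tracks round-trip through signal and rheology at zero noise", {
  f_vol <- 2.59e5
  obs <- rbind(single_obs(129.5, 5.46), single_obs(80.79, 44.09))
  obs$sphere <- c("t1", "t2")
  tracks <- gen_matrix_tracks(obs, f_vol, noise_sd_m = 0, seed = 1)
  # amplitude for |G| = 129.5 Pa, D = 30 um: F*D^2/(18|G|) = 100 nm
  t1 <- tracks[tracks$sphere == "t1", ]
  expect_equal(max(abs(t1$displacement_m)), 100e-9, tolerance = 1e-6)
  fits <- fit_tracks(tracks)
  rec <- tracks_to_observations(fits, f_vol)
  rec <- rec[order(rec$sphere), ]
  expect_equal(rec$abs_shear_modulus_pa, c(129.5, 80.79), tolerance = 1e-10)
  expect_equal(rec$phase_deg, c(5.46, 44.09), tolerance = 1e-8)

  expect_identical(tracks, gen_matrix_tracks(obs, f_vol, noise_sd_m = 0, seed = 1))
  bad <- obs; bad$abs_shear_modulus_pa <- 0
  expect_error(gen_matrix_tracks(bad, f_vol), "> 0")
})

test_that("visco observation generator carries both responses and ground truth", {
  obs <- gen_visco_observations(hierarchy_design(2, 2, 2, 2, 2), seed = 4)
  expect_true(all(c("abs_shear_modulus_pa", "phase_deg", "diameter_um") %in% names(obs)))
  tr <- attr(obs, "truth")
  expect_equal(tr$seed, 4)
  # diameters constant within a sphere across repeats
  per_sphere <- tapply(obs$diameter_um,
                       paste(obs$sample, obs$holder, obs$location, obs$sphere),
                       function(x) diff(range(x)))
  expect_true(all(per_sphere == 0))
  expect_identical(obs, gen_visco_observations(hierarchy_design(2, 2, 2, 2, 2), seed = 4))
})
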