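test_that("sinusoid fit recovers pure signals exactly", {
  t <- seq(0, 40, by = 0.04)
  f <- 0.05
  # in-phase: p = sin(wt) => amplitude 1, phase 0
  fit <- fit_sinusoid(t, sin(2 * pi * f * t), f)
  expect_equal(fit$amplitude_m, 1, tolerance = 1e-10)
  expect_equal(fit$phase_deg, 0, tolerance = 1e-8)
  # quadrature: p = -cos(wt) = sin(wt - 90 deg), the purely viscous case
  fit <- fit_sinusoid(t, -cos(2 * pi * f * t), f)
  expect_equal(fit$phase_deg, 90, tolerance = 1e-8)
  # general known amplitude/phase
  p <- 3.5e-7 * sin(2 * pi * f * t - 30 * pi / 180)
  fit <- fit_sinusoid(t, p, f)
  expect_equal(fit$amplitude_m, 3.5e-7, tolerance = 1e-10)
  expect_equal(fit$phase_deg, 30, tolerance = 1e-8)
})

test_that("fit is invariant to constant offsets and, with drift term, to ramps", {
  t <- seq(0, 20, by = 0.04)
  f <- 0.05
  base <- 1e-7 * sin(2 * pi * f * t - 0.4)
  ref <- fit_sinusoid(t, base, f)
  shifted <- fit_sinusoid(t, base + 5e-6, f)
  ramped <- fit_sinusoid(t, base + 5e-6 + 3e-8 * t, f, include_drift = TRUE)
  expect_equal(shifted$amplitude_m, ref$amplitude_m, tolerance = 1e-10)
  expect_equal(shifted$phase_deg, ref$phase_deg, tolerance = 1e-8)
  expect_equal(ramped$amplitude_m, ref$amplitude_m, tolerance = 1e-10)
  expect_equal(ramped$phase_deg, ref$phase_deg, tolerance = 1e-8)
})

test_that("noisy fit matches a dense grid-search oracle", {
  set.seed(99)
  f <- 0.05
  t <- seq(0, 20, length.out = 500)
  truth_amp <- 100e-9; truth_phase <- 30
  y <- truth_amp * sin(2 * pi * f * t - truth_phase * pi / 180) +
    rnorm(500, 0, 10e-9)
  fit <- fit_sinusoid(t, y, f, include_drift = FALSE)
  # brute-force oracle over (amplitude, phase), offset profiled out
  amps <- seq(80e-9, 120e-9, by = 0.25e-9)
  phases <- seq(20, 40, by = 0.05)
  sse <- outer(amps, phases, Vectorize(function(a, ph) {
    r <- y - a * sin(2 * pi * f * t - ph * pi / 180)
    sum((r - mean(r))^2)
  }))
  best <- arrayInd(which.min(sse), dim(sse))
  expect_equal(fit$amplitude_m, amps[best[1]], tolerance = 0.25e-9 / truth_amp)
  expect_equal(fit$phase_deg, phases[best[2]], tolerance = 0.06 / 30)
})

test_that("reference correction removes common-mode motion", {
  t <- seq(0, 20, by = 0.04)
  f <- 0.05
  signal <- 1e-7 * sin(2 * pi * f * t - 0.3)
  # magnetic identical to references -> zero displacement
  expect_equal(relative_displacement(t, signal, cbind(signal, signal)),
               rep(0, length(t)), tolerance = 1e-15)
  # a shared ramp leaves the corrected track unchanged
  ramp <- 2e-7 * t
  plain <- relative_displacement(t, signal, cbind(0 * t, 0 * t))
  with_ramp <- relative_displacement(t, signal + ramp, cbind(ramp, ramp))
  expect_equal(with_ramp, plain, tolerance = 1e-12)
  # broadband shared vibration: residual common-mode power < 1% of injected
  set.seed(5)
  vib <- as.numeric(stats::filter(rnorm(length(t), 0, 5e-8), rep(1, 5),
                                  circular = TRUE))
  corrected <- relative_displacement(t, signal + vib, cbind(vib, vib))
  resid <- corrected - (signal - signal[1]) -
    mean(corrected - (signal - signal[1]))
  expect_lt(mean(resid^2), 0.01 * mean((vib - mean(vib))^2))
  expect_error(relative_displacement(t, signal, NULL), "reference")
})

test_that("degenerate signals are flagged and short tracks rejected", {
  t <- seq(0, 20, by = 0.04)
  fit <- fit_sinusoid(t, rep(2e-7, length(t)), 0.05)
  expect_equal(fit$amplitude_m, 0)
  expect_false(fit$phase_defined)
  expect_error(fit_sinusoid(c(0, 10, 20, 30), 1:4 * 1e-9, 0.05), "parameters")
  expect_error(fit_sinusoid(seq(0, 5, 1), rnorm(6), 0.05), "period")
})

test_that("velocity amplitude follows v = 2*pi*f*p", {
  expect_equal(velocity_amplitude(0, drive_config()), 0)
  expect_equal(velocity_amplitude(1, drive_config(frequency_hz = 1 / (2 * pi))), 1)
  expect_equal(velocity_amplitude(1.374e-6, drive_config(frequency_hz = 0.05)),
               2 * pi * 0.05 * 1.374e-6)
})

test_that("qc filter partitions exactly at the thresholds with reasons", {
  fits <- data.frame(sphere = letters[1:4],
                     snr = c(10, 2, 10, 1), r2 = c(0.9, 0.9, 0.3, 0.2))
  res <- qc_filter(fits, min_snr = 3, min_r2 = 0.5)
  expect_equal(res$accepted$sphere, "a")
  expect_equal(res$rejected$reason, c("low_snr", "low_r2", "low_snr;low_r2"))
  expect_equal(unname(res$counts["rejected"]), 3)
  # direct recomputation of the partition
  expect_equal(res$accepted$sphere,
               fits$sphere[fits$snr >= 3 & fits$r2 >= 0.5])
  # everything passes / everything fails
  expect_equal(nrow(qc_filter(fits, min_snr = 0, min_r2 = 0)$rejected), 0)
  expect_equal(nrow(qc_filter(fits, min_snr = Inf, min_r2 = 0)$accepted), 0)
})
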