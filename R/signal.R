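# Signal stage: reference-sphere correction, sinusoid fitting at the known
# drive frequency, and SNR/R^2 quality filtering.

#' Relative displacement against reference spheres
#'
#' Removes mounting-related and environmental common-mode motion by
#' subtracting the mean of one or more non-magnetic reference-sphere position
#' series from the magnetic-sphere positions, then re-zeroes the result to
#' its first sample. All series must share a common time base.
#'
#' @param time_s Time stamps (s), strictly increasing.
#' @param magnetic_m Magnetic-sphere raw positions (m).
#' @param reference_m Reference positions: a numeric vector (one reference
#'   sphere) or a matrix with one column per reference sphere.
#' @return Numeric vector of relative displacements (m), zero at the first
#'   sample.
#' @export
relative_displacement <- function(time_s, magnetic_m, reference_m) {
  abort_if(is.null(reference_m) || length(reference_m) == 0,
           "at least one reference track is required to remove common-mode motion")
  ref <- as.matrix(reference_m)
  abort_if(nrow(ref) != length(magnetic_m) || length(time_s) != length(magnetic_m),
           "magnetic, reference and time series must share a common time base")
  abort_if(any(diff(time_s) <= 0), "time_s must be strictly increasing")
  rel <- magnetic_m - rowMeans(ref)
  rel - rel[1]
}

#' Fit a sinusoid of known frequency to a displacement track
#'
#' Least-squares fit of `p_hat * sin(2*pi*f*t - phi)` (plus a constant offset
#' and, optionally, a linear drift term) via the linear basis
#' `a*sin(2*pi*f*t) + b*cos(2*pi*f*t)`, so the fit is convex and needs no
#' initialization. Amplitude is `sqrt(a^2 + b^2)` and the phase
#' `phi = atan2(-b, a)`, so a displacement lagging the force drive has
#' positive phase (0 deg purely elastic, 90 deg purely viscous).
#'
#' @param time_s Time stamps (s); must span at least one full drive period.
#' @param displacement_m Displacement samples (m).
#' @param frequency_hz Known drive frequency (Hz).
#' @param include_drift Include a linear drift regressor (default TRUE).
#' @return An object of class `sinusoid_fit`: `amplitude_m`, `phase_deg`
#'   (wrapped to \[-180, 180); `NA` and flagged when the signal has zero
#'   variance), `residual_sd_m`, `r2`, `snr` (amplitude / residual SD),
#'   `coefficients` and `n`.
#' @export
fit_sinusoid <- function(time_s, displacement_m, frequency_hz,
                         include_drift = TRUE) {
  check_positive(frequency_hz, "frequency_hz")
  n <- length(time_s)
  abort_if(n != length(displacement_m), "time and displacement lengths differ")
  abort_if(diff(range(time_s)) < 1 / frequency_hz - 1e-9,
           "track must span at least one full drive period")
  w <- 2 * pi * frequency_hz
  X <- cbind(sin = sin(w * time_s), cos = cos(w * time_s), offset = 1)
  if (include_drift) X <- cbind(X, drift = time_s)
  p <- ncol(X)
  abort_if(n <= p, "fewer data points than fit parameters")

  if (stats::var(displacement_m) == 0) {
    return(structure(list(amplitude_m = 0, phase_deg = NA_real_,
                          phase_defined = FALSE, residual_sd_m = 0,
                          r2 = NA_real_, snr = NA_real_,
                          coefficients = stats::setNames(rep(0, p), colnames(X)),
                          frequency_hz = frequency_hz, n = n),
                     class = "sinusoid_fit"))
  }

  fit <- stats::lm.fit(X, displacement_m)
  cf <- fit$coefficients
  a <- cf[["sin"]]; b <- cf[["cos"]]
  amplitude <- sqrt(a^2 + b^2)
  phase <- wrap_degrees(atan2(-b, a) * 180 / pi)
  rss <- sum(fit$residuals^2)
  tss <- sum((displacement_m - mean(displacement_m))^2)
  residual_sd <- sqrt(rss / (n - p))
  structure(list(amplitude_m = amplitude, phase_deg = phase,
                 phase_defined = TRUE, residual_sd_m = residual_sd,
                 r2 = 1 - rss / tss,
                 snr = if (residual_sd > 0) amplitude / residual_sd else Inf,
                 coefficients = cf, frequency_hz = frequency_hz, n = n),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("sinusoid fit @ %g Hz: amplitude %.4g nm, phase %.2f deg, SNR %.1f, R2 %.4f\n",
              x$frequency_hz, x$amplitude_m * 1e9,
              if (x$phase_defined) x$phase_deg else NA, x$snr, x$r2))
  invisible(x)
}

#' Velocity amplitude from a displacement fit
#'
#' For a sinusoid of amplitude `p_hat` at drive frequency `f`, the velocity
#' amplitude is `v_hat = 2*pi*f*p_hat`.
#'
#' @param fit A `sinusoid_fit`, or a numeric displacement amplitude (m).
#' @param drive A [drive_config()] (required when `fit` is numeric).
#' @return Velocity amplitude (m/s).
#' @export
velocity_amplitude <- function(fit, drive = NULL) {
  if (inherits(fit, "sinusoid_fit")) {
    2 * pi * fit$frequency_hz * fit$amplitude_m
  } else {
    stopifnot(inherits(drive, "drive_config"))
    2 * pi * drive$frequency_hz * fit
  }
}

#' Fit every track in a tidy track table
#'
#' Applies [fit_sinusoid()] independently to each
#' (matrix, sample, holder, location, sphere, repeat) track.
#'
#' @param tracks Tidy track data frame (schema of [gen_matrix_tracks()]).
#' @param drive A [drive_config()] giving the drive frequency.
#' @param include_drift Passed to [fit_sinusoid()].
#' @return Data frame with one row per repeat: hierarchy labels,
#'   `diameter_um`, `amplitude_m`, `phase_deg`, `residual_sd_m`, `snr`, `r2`.
#' @export
fit_tracks <- function(tracks, drive = drive_config(), include_drift = TRUE) {
  check_columns(tracks, track_columns, "tracks")
  key <- interaction(tracks$matrix, tracks$sample, tracks$holder,
                     tracks$location, tracks$sphere, tracks$`repeat`,
                     drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(tracks)), key)
  rows <- lapply(groups, function(idx) {
    g <- tracks[idx, ]
    g <- g[order(g$time_s), ]
    fit <- fit_sinusoid(g$time_s, g$displacement_m, drive$frequency_hz,
                        include_drift = include_drift)
    data.frame(g[1, c("matrix", "sample", "holder", "location", "sphere", "repeat")],
               diameter_um = g$diameter_um[1],
               amplitude_m = fit$amplitude_m, phase_deg = fit$phase_deg,
               residual_sd_m = fit$residual_sd_m, snr = fit$snr, r2 = fit$r2,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$matrix, out$sample, out$holder, out$location, out$sphere,
            out$`repeat`), , drop = FALSE]
}

#' Quality filter on fitted tracks
#'
#' Deterministically partitions a fit table into accepted and rejected rows.
#' A fit is rejected when its SNR or R^2 falls below threshold (a low
#' displacement signal-to-noise ratio is the practical failure mode in stiff
#' matrices); every rejection carries a machine-readable reason.
#'
#' @param fits Fit table from [fit_tracks()].
#' @param min_snr Minimum amplitude / residual-SD ratio (default 3).
#' @param min_r2 Minimum coefficient of determination (default 0.5).
#' @return List with `accepted` (fit rows), `rejected` (fit rows plus a
#'   `reason` column) and `counts`.
#' @export
qc_filter <- function(fits, min_snr = 3, min_r2 = 0.5) {
  # Inf is a legal threshold (reject everything)
  abort_if(is.na(min_snr) || min_snr < 0, "`min_snr` must be >= 0")
  abort_if(is.na(min_r2) || min_r2 < 0, "`min_r2` must be >= 0")
  check_columns(fits, c("snr", "r2"), "fits")
  snr_bad <- !is.finite(fits$snr) | fits$snr < min_snr
  # Inf snr (zero residual) passes any finite threshold
  snr_bad[is.infinite(fits$snr) & fits$snr > 0 & is.finite(min_snr)] <- FALSE
  r2_bad <- !is.finite(fits$r2) | fits$r2 < min_r2
  reason <- ifelse(snr_bad & r2_bad, "low_snr;low_r2",
                   ifelse(snr_bad, "low_snr", ifelse(r2_bad, "low_r2", "")))
  rejected <- fits[reason != "", , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[reason != ""]
  else rejected$reason <- character(0)
  accepted <- fits[reason == "", , drop = FALSE]
  list(accepted = accepted, rejected = rejected,
       counts = c(total = nrow(fits), accepted = nrow(accepted),
                  rejected = nrow(rejected)))
}
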