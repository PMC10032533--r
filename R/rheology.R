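# Rheology stage: closed-form conversions from fitted amplitudes to
# viscoelastic quantities and the summary arithmetic used for
# cross-technique comparisons.

#' Absolute shear modulus from a displacement amplitude
#'
#' Generalized-Stokes relation for an oscillating sphere in a viscoelastic
#' medium: `|G| = F_vol * V / (3 * pi * D * p_hat)`, which simplifies to
#' `F_vol * D^2 / (18 * p_hat)`.
#'
#' @param amplitude_m Fitted displacement amplitude p_hat (m), > 0.
#' @param diameter_m Sphere diameter (m).
#' @param f_volumetric Calibrated volumetric force constant (N/m^3).
#' @return Absolute shear modulus in Pa.
#' @export
shear_modulus <- function(amplitude_m, diameter_m, f_volumetric) {
  abort_if(any(!is.finite(amplitude_m) | amplitude_m <= 0),
           "amplitude must be > 0: an unresolvable displacement signals an SNR failure")
  check_positive(diameter_m, "diameter_m")
  check_positive(f_volumetric, "f_volumetric")
  f_volumetric * diameter_m^2 / (18 * amplitude_m)
}

#' Young's modulus from shear modulus
#'
#' Isotropic linear-elastic conversion `E = 2 * (1 + v) * |G|`; an SD of |G|
#' maps to an SD of E by the same factor.
#'
#' @param g_pa Absolute shear modulus (Pa); may be a mean or an SD.
#' @param poisson_ratio Poisson's ratio v in \[0, 0.5\] (0.37-0.50 is the
#'   range used for agarose).
#' @return Young's modulus in Pa.
#' @export
youngs_modulus <- function(g_pa, poisson_ratio) {
  abort_if(any(!is.finite(poisson_ratio) | poisson_ratio < 0 | poisson_ratio > 0.5),
           "poisson_ratio must lie in [0, 0.5]")
  2 * (1 + poisson_ratio) * g_pa
}

#' Expected shear-modulus ratio between two sphere sizes
#'
#' At equal displacement amplitude, a sphere of diameter `d2` reports
#' `(fv2/fv1) * (d2/d1)^2` times the shear modulus of a sphere of diameter
#' `d1` (each size using its own calibrated volumetric force constant).
#'
#' @param d1,d2 Sphere diameters (any common unit).
#' @param fv1,fv2 Volumetric force constants for the two sizes (N/m^3).
#' @return Dimensionless ratio |G(d2)| / |G(d1)|.
#' @export
expected_modulus_ratio <- function(d1, d2, fv1, fv2) {
  check_positive(c(d1, d2, fv1, fv2), "diameters and force constants")
  (fv2 / fv1) * (d2 / d1)^2
}

#' Coefficient of variation
#'
#' @param mean Mean value (non-zero).
#' @param sd Standard deviation.
#' @return `sd / mean`.
#' @export
coefficient_of_variation <- function(mean, sd) {
  abort_if(any(mean == 0), "coefficient of variation is undefined for zero mean")
  sd / mean
}

#' Convert a fit table into viscoelastic observations
#'
#' Composes the sinusoid-fit amplitudes with the calibrated force constant:
#' one (|G|, phase) observation per sphere per repeat, with Young's modulus
#' attached for both ends of the Poisson-ratio range. Mixed sphere sizes use
#' their own calibration constants, matched on nominal diameter.
#'
#' @param fits Fit table from [fit_tracks()] (must carry `diameter_um`).
#' @param f_volumetric Either a single constant (N/m^3) applied to all rows,
#'   or a data frame with columns `nominal_diameter_um` and `f_volumetric`;
#'   rows are matched to the nearest nominal diameter.
#' @param poisson_range Two-element Poisson-ratio range (default
#'   `c(0.37, 0.50)`).
#' @return Observation data frame: hierarchy labels, `diameter_um`,
#'   `abs_shear_modulus_pa`, `phase_deg`, `phase_flag` (TRUE when the phase
#'   falls outside \[0, 90\] deg — flagged, never dropped),
#'   `youngs_modulus_low_kpa`, `youngs_modulus_high_kpa`. Rows whose
#'   amplitude is non-positive or whose calibration/diameter is missing are
#'   dropped and reported in attribute `"errors"` (with a reason each).
#' @export
tracks_to_observations <- function(fits, f_volumetric,
                                   poisson_range = c(0.37, 0.50)) {
  check_columns(fits, c("matrix", "sample", "holder", "location", "sphere",
                        "repeat", "diameter_um", "amplitude_m", "phase_deg"),
                "fits")
  stopifnot(length(poisson_range) == 2)
  fv <- rep(NA_real_, nrow(fits))
  if (is.data.frame(f_volumetric)) {
    check_columns(f_volumetric, c("nominal_diameter_um", "f_volumetric"),
                  "calibration table")
    idx <- vapply(fits$diameter_um, function(d) {
      if (!is.finite(d)) return(NA_integer_)
      which.min(abs(f_volumetric$nominal_diameter_um - d))
    }, integer(1))
    fv <- f_volumetric$f_volumetric[idx]
  } else {
    check_positive(f_volumetric, "f_volumetric")
    fv[] <- f_volumetric
  }
  reason <- rep("", nrow(fits))
  reason[!is.finite(fits$diameter_um) | fits$diameter_um <= 0] <- "missing_diameter"
  reason[!is.finite(fv)] <- "missing_calibration"
  ok_amp <- is.finite(fits$amplitude_m) & fits$amplitude_m > 0
  reason[reason == "" & !ok_amp] <- "nonpositive_amplitude"

  keep <- reason == ""
  errors <- fits[!keep, , drop = FALSE]
  if (nrow(errors) > 0) errors$reason <- reason[!keep]
  f <- fits[keep, , drop = FALSE]
  fv <- fv[keep]
  g <- if (nrow(f) > 0) shear_modulus(f$amplitude_m, f$diameter_um * 1e-6, fv)
       else numeric(0)
  out <- data.frame(
    f[c("matrix", "sample", "holder", "location", "sphere", "repeat")],
    diameter_um = f$diameter_um,
    abs_shear_modulus_pa = g,
    phase_deg = f$phase_deg,
    phase_flag = !is.na(f$phase_deg) & (f$phase_deg < 0 | f$phase_deg > 90),
    youngs_modulus_low_kpa = youngs_modulus(g, min(poisson_range)) / 1000,
    youngs_modulus_high_kpa = youngs_modulus(g, max(poisson_range)) / 1000,
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(errors) > 0) {
    warning(nrow(errors), " row(s) dropped during conversion; see attr(x, 'errors')",
            call. = FALSE)
  }
  attr(out, "errors") <- errors
  out
}
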