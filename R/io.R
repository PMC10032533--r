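# File formats: tidy CSV for tracks / fits / observations, YAML run
# configuration, JSON summaries and provenance. Hierarchy labels are always
# strings, never positional integers, so indices cannot silently drift
# between stages.

#' Read a tidy track table
#'
#' Header-driven CSV reader for the track schema (`matrix, sample, holder,
#' location, sphere, repeat, time_s, displacement_m, diameter_um`). Columns
#' may appear in any order. Rows are validated: non-empty labels, positive
#' diameters, strictly increasing time within each track; offending rows are
#' reported with their file line numbers.
#'
#' @param path CSV file path.
#' @return Track data frame with label columns as character.
#' @export
read_tracks <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, track_columns, basename(path))
  df <- df[track_columns]
  for (col in c("matrix", "sample", "holder", "location", "sphere", "repeat")) {
    df[[col]] <- as.character(df[[col]])
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  problems <- character(0)
  bad_label <- !stats::complete.cases(df[1:6]) |
    Reduce(`|`, lapply(df[1:6], function(x) !nzchar(x)))
  if (any(bad_label)) {
    problems <- c(problems, paste0("line ", line[bad_label][1],
                                   ": empty or missing hierarchy label"))
  }
  bad_diam <- !is.finite(df$diameter_um) | df$diameter_um <= 0
  if (any(bad_diam)) {
    problems <- c(problems, paste0("line ", line[bad_diam][1],
                                   ": non-positive diameter_um"))
  }
  key <- paste(df$matrix, df$sample, df$holder, df$location, df$sphere,
               df$`repeat`, sep = "|")
  for (idx in split(seq_len(nrow(df)), key)) {
    tt <- df$time_s[idx]
    nonmono <- which(diff(tt) <= 0)
    if (length(nonmono) > 0) {
      problems <- c(problems, paste0("line ", line[idx[nonmono[1] + 1]],
                                     ": time_s not strictly increasing within track"))
    }
  }
  abort_if(length(problems) > 0, "invalid track file:\n  ",
           paste(problems, collapse = "\n  "))
  df
}

#' Write a tidy track table
#' @param tracks Track data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  check_columns(tracks, track_columns, "tracks")
  utils::write.csv(tracks[track_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read / write viscoelastic observation tables
#'
#' Observation CSVs carry the hierarchy labels plus `diameter_um`,
#' `abs_shear_modulus_pa` and `phase_deg` (any further columns are kept).
#'
#' @param path CSV file path.
#' @return Observation data frame.
#' @export
read_observations <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, obs_columns, basename(path))
  for (col in c("matrix", "sample", "holder", "location", "sphere", "repeat")) {
    df[[col]] <- as.character(df[[col]])
  }
  df
}

#' @rdname read_observations
#' @param observations Observation data frame.
#' @export
write_observations <- function(observations, path) {
  check_columns(observations, obs_columns, "observations")
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a YAML run configuration
#'
#' The run configuration bundles the drive waveform, calibration fluid,
#' calibration constants per nominal sphere size, the Poisson-ratio range,
#' QC thresholds, model settings and the seed. Schema violations fail before
#' any computation runs.
#'
#' @param path YAML file path.
#' @return List of class `run_config` with typed sub-objects.
#' @export
read_run_config <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- validate_run_config(raw)
  cfg$fingerprint <- config_fingerprint(paste(readLines(path), collapse = "\n"))
  cfg
}

validate_run_config <- function(raw) {
  abort_if(!is.list(raw), "config must be a YAML mapping")
  dr <- raw$drive %||% list()
  drive <- drive_config(frequency_hz = dr$frequency_hz %||% 0.05,
                        i_grad_amp = dr$i_grad_amp %||% 1.25,
                        i_offset = dr$i_offset %||% 0.75)
  fl <- raw$fluid %||% list()
  fluid <- fluid_properties(
    dynamic_viscosity_pa_s = fl$dynamic_viscosity_pa_s %||% 30,
    temperature_note = fl$temperature_note %||% "room temperature")
  cal <- raw$calibration %||% list()
  cal_tab <- NULL
  if (!is.null(cal$constants)) {
    cal_tab <- do.call(rbind, lapply(cal$constants, function(x) {
      abort_if(is.null(x$nominal_diameter_um) || is.null(x$f_volumetric),
               "each calibration constant needs nominal_diameter_um and f_volumetric")
      data.frame(nominal_diameter_um = x$nominal_diameter_um,
                 f_volumetric = x$f_volumetric)
    }))
    check_positive(cal_tab$f_volumetric, "f_volumetric")
  }
  poisson <- unlist(raw$poisson_range %||% c(0.37, 0.50))
  abort_if(length(poisson) != 2 || any(poisson < 0 | poisson > 0.5),
           "poisson_range must be two values in [0, 0.5]")
  qc <- raw$qc %||% list()
  mc <- raw$mcmc %||% list()
  seed <- raw$seed %||% 1
  mcmc <- mcmc_config(chains = mc$chains %||% 4, warmup = mc$warmup %||% 1000,
                      iter = mc$iter %||% 1000, seed = mc$seed %||% seed)
  model <- raw$model %||% list()
  structure(list(
    drive = drive, fluid = fluid, calibration_constants = cal_tab,
    poisson_range = as.numeric(poisson),
    qc = list(min_snr = qc$min_snr %||% 3, min_r2 = qc$min_r2 %||% 0.5),
    mcmc = mcmc,
    model = list(variant = model$variant %||% "primary",
                 response = model$response %||% "abs_shear_modulus_pa",
                 noise_parametrization = model$noise_parametrization %||% "shape_scale"),
    seed = as.integer(seed), raw = raw), class = "run_config")
}

#' Write a provenance block next to an artifact
#'
#' Records everything needed to reproduce an output: the full configuration,
#' its fingerprint, the seed, package and R versions and a timestamp.
#'
#' @param path Output JSON path.
#' @param config A `run_config` (or any serializable list).
#' @param seed Seed used for the stage.
#' @param extra Optional named list of stage-specific fields (e.g. per-stage
#'   counts of spheres read / QC-rejected / observations fitted).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed, extra = list()) {
  block <- c(list(
    package = "magrheo",
    package_version = as.character(utils::packageVersion("magrheo")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_fingerprint = if (inherits(config, "run_config"))
      config$fingerprint %||% NA_character_ else config_fingerprint(
        jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)),
    config = if (inherits(config, "run_config")) config$raw else config),
    extra)
  jsonlite::write_json(block, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Export posterior draws to a columnar file
#'
#' @param fit A `heterogeneity_fit` or `calibration_fit`.
#' @param path Output CSV path (one column per parameter, one row per draw).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  draws <- if (inherits(fit, "heterogeneity_fit")) fit$draws
           else if (inherits(fit, "calibration_fit")) as.data.frame(fit$draws)
           else stop("unsupported fit object", call. = FALSE)
  utils::write.csv(as.data.frame(draws), path, row.names = FALSE)
  invisible(path)
}
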