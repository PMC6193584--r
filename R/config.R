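#' Generative configuration for the synthetic study
#'
#' Holds every parameter of the synthetic badge-sensor study: the roster size
#' and segment structure, the location/speech/movement/ambient stream
#' processes, the task-demand distributions, and the two latent exertion
#' models (mental and physical) whose ground truth is recorded for recovery
#' testing.
#'
#' Defaults encode the reference study conditions: 35 twelve-hour day shifts
#' split into three four-hour segments, with a per-segment rating dropout of
#' 16/105 so the expected number of rated segments is 89; 70% weekday shifts;
#' and exertion models whose term structure, coefficients and variance
#' components follow the final mental- and physical-exertion models
#' (random shift intercept, one random slope each, one cross-level
#' interaction each).
#'
#' @param n_shifts Number of shifts in the roster.
#' @param segments_per_shift Four-hour segments per shift.
#' @param segment_length Segment length in seconds.
#' @param frame_rate Wearable frame rate in Hz (speech and accelerometer).
#' @param ambient_rate Stationary-sensor frame rate in Hz.
#' @param dropout Probability that a segment's exertion ratings are missing.
#' @param weekend_prob Probability a shift falls on a weekend.
#' @param location Location process parameters: mean dwell seconds per zone
#'   class, a class-to-class transition matrix, the gamma shape of dwell
#'   times, and the log-scale SD of per-shift dwell multipliers.
#' @param speech Speech on/off renewal process: mean episode seconds, mean
#'   gap seconds, gap distribution (`"pareto"` for bursty speaking or
#'   `"exponential"` for Poisson-like), Pareto tail index, volume and pitch
#'   baselines, and per-shift effect SDs.
#' @param accel Accelerometer magnitudes: per-class baselines (g), frame
#'   noise SD, walking-bout level and duration, in-room activity bout rate,
#'   and per-shift effect SD.
#' @param ambient Ambient noise (dB) and temperature (C) baselines per
#'   instrumented class, frame SDs, and per-shift effect SDs.
#' @param demands Task-demand distributions (see [generate_roster()]).
#' @param me_model,pe_model Latent exertion models: named coefficient vector
#'   on standardised features (`"a:b"` names denote products), variance
#'   components `var_u0` (between-shift intercept), `var_e` (residual),
#'   `var_u1` and `slope_feature` (one random slope), `cov_u01`, and
#'   `intercept`.
#' @param borg Affine map from the latent standardised scale to the Borg 6-20
#'   scale: `rating = round(center + scale * latent)`, clamped.
#' @param feature_icc Named overrides of the intraclass correlation used by
#'   the direct feature simulator [simulate_features()].
#' @param seed Default seed used when none is supplied to the generators.
#' @return A list of class `generative_config`.
#' @export
generative_config <- function(n_shifts = 35L,
                              segments_per_shift = 3L,
                              segment_length = 14400,
                              frame_rate = 1,
                              ambient_rate = 1 / 60,
                              dropout = 16 / 105,
                              weekend_prob = 0.3,
                              location = list(),
                              speech = list(),
                              accel = list(),
                              ambient = list(),
                              demands = list(),
                              me_model = list(),
                              pe_model = list(),
                              borg = list(center = 13, scale = 3),
                              feature_icc = NULL,
                              seed = 1L) {
  loc_default <- list(
    dwell_mean = c(patient_room = 600, nursing_station = 300,
                   service_area = 150, off_main = 240),
    dwell_shape = 2,
    transition = matrix(c(0.25, 0.35, 0.25, 0.15,
                          0.50, 0.10, 0.20, 0.20,
                          0.50, 0.30, 0.00, 0.20,
                          0.40, 0.35, 0.25, 0.00),
                        4, 4, byrow = TRUE,
                        dimnames = list(zone_classes, zone_classes)),
    shift_dwell_sd = 0.9
  )
  speech_default <- list(
    episode_mean = 8, gap_mean = 40, gap_dist = "pareto", pareto_shape = 1.15,
    volume_mean = 60, volume_sd = 3, shift_volume_sd = 3,
    segment_volume_sd = 2.5,
    pitch_mean = 180, pitch_sd = 15, shift_pitch_sd = 20,
    segment_pitch_sd = 10,
    shift_gap_sd = 0.30
  )
  accel_default <- list(
    baseline = c(patient_room = 0.16, nursing_station = 0.07,
                 service_area = 0.14, off_main = 0.11),
    frame_sd = 0.05, shift_sd = 0.07,
    walk_level = 0.32, walk_sd = 0.05,
    walk_duration = c(15, 60), room_bout_rate = 6 / 3600,
    room_bout_duration = c(30, 120)
  )
  ambient_default <- list(
    noise = c(patient_room = 55, nursing_station = 62, service_area = 58),
    noise_sd = 2.5, shift_noise_sd = 4, segment_noise_sd = 1.5,
    temperature = c(patient_room = 22, nursing_station = 23,
                    service_area = 21),
    temperature_sd = 0.4, shift_temperature_sd = 0.8,
    segment_temperature_sd = 0.4
  )
  demands_default <- list(
    n_patients_levels = 1:3, n_patients_probs = c(0.2, 0.6, 0.2),
    sitter_prob = 0.15, assistant_prob = 0.4,
    factor_probs = c(patients_on_insulin_drip = 0.30,
                     patients_on_ventilator = 0.45,
                     patients_on_dialysis = 0.15,
                     patients_restrained = 0.20,
                     patients_in_isolation = 0.25,
                     patients_post_op = 0.50,
                     patients_with_delirium = 0.20,
                     patients_with_wound_care = 0.35),
    load_noise_sd = 0.3
  )
  me_default <- list(
    coefficients = c(
      noise_patient_rooms = 0.30,
      time_outside_main = 0.23,
      activity_outside_main = -0.32,
      "time_outside_main:activity_outside_main" = 0.60,
      burstiness_speaking = 0.03,
      patients_on_insulin_drip = 0.05,
      "patients_on_insulin_drip:burstiness_speaking" = 0.19),
    var_u0 = 0.17, var_e = 0.36,
    slope_feature = "burstiness_speaking", var_u1 = 0.02, cov_u01 = 0,
    intercept = 0
  )
  pe_default <- list(
    coefficients = c(
      entropy_transitions = 0.15,
      burstiness_transitions = -0.03,
      time_speaking_outside_main = 0.03,
      volume_speaking_nursing_stations = 0.05,
      time_nursing_stations = 0.17,
      noise_service_areas = 0.18,
      time_walking_patient_rooms = 0.12,
      "entropy_transitions:burstiness_transitions" = 0.22,
      "time_speaking_outside_main:time_nursing_stations" = 0.37,
      "noise_service_areas:time_walking_patient_rooms" = -0.19,
      average_patient_load = -0.05,
      "average_patient_load:volume_speaking_nursing_stations" = 0.30),
    var_u0 = 0.25, var_e = 0.20,
    slope_feature = "volume_speaking_nursing_stations", var_u1 = 0.16,
    cov_u01 = 0,
    intercept = 0
  )

  cfg <- list(
    n_shifts = as.integer(n_shifts),
    segments_per_shift = as.integer(segments_per_shift),
    segment_length = segment_length,
    frame_rate = frame_rate,
    ambient_rate = ambient_rate,
    dropout = dropout,
    weekend_prob = weekend_prob,
    location = modifyList(loc_default, location),
    speech = modifyList(speech_default, speech),
    accel = modifyList(accel_default, accel),
    ambient = modifyList(ambient_default, ambient),
    demands = modifyList(demands_default, demands),
    me_model = modifyList(me_default, me_model),
    pe_model = modifyList(pe_default, pe_model),
    borg = modifyList(list(center = 13, scale = 3), borg),
    feature_icc = feature_icc,
    seed = as.integer(seed)
  )
  class(cfg) <- "generative_config"
  validate_generative_config(cfg)
  cfg
}

validate_generative_config <- function(cfg) {
  err <- function(...) stop("invalid generative config: ", sprintf(...),
                            call. = FALSE)
  if (cfg$n_shifts < 0) err("n_shifts must be >= 0")
  if (cfg$segments_per_shift < 1) err("segments_per_shift must be >= 1")
  if (cfg$segment_length <= 0) err("segment_length must be positive")
  if (cfg$dropout < 0 || cfg$dropout > 1) err("dropout must be in [0, 1]")
  if (cfg$weekend_prob < 0 || cfg$weekend_prob > 1) {
    err("weekend_prob must be in [0, 1]")
  }
  tm <- cfg$location$transition
  if (!all(dim(tm) == c(4, 4)) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-8)) {
    err("location transition matrix must be 4x4 row-stochastic")
  }
  if (any(cfg$location$dwell_mean <= 0)) err("dwell means must be positive")
  if (!cfg$speech$gap_dist %in% c("exponential", "pareto")) {
    err("speech gap_dist must be 'exponential' or 'pareto'")
  }
  if (cfg$speech$pareto_shape <= 1) {
    err("pareto_shape must exceed 1 so inter-episode gaps have a finite mean")
  }
  for (m in c("me_model", "pe_model")) {
    mod <- cfg[[m]]
    if (mod$var_u0 < 0 || mod$var_e < 0 || mod$var_u1 < 0) {
      err("%s variance components must be non-negative", m)
    }
    if (mod$var_u1 > 0 &&
        mod$cov_u01^2 > mod$var_u0 * mod$var_u1 + 1e-12) {
      err("%s intercept-slope covariance is not positive semi-definite", m)
    }
  }
  invisible(cfg)
}

#' Read a generative configuration from a YAML file
#'
#' Keys mirror the arguments of [generative_config()]; nested keys override
#' individual defaults (e.g. `speech: {gap_dist: exponential}`).
#'
#' @param path Path to a YAML file.
#' @return A `generative_config`.
#' @export
read_generative_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generative_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$location$transition)) {
    raw$location$transition <- matrix(unlist(raw$location$transition), 4, 4,
                                      byrow = TRUE,
                                      dimnames = list(zone_classes,
                                                      zone_classes))
  }
  for (m in c("me_model", "pe_model")) {
    if (!is.null(raw[[m]]$coefficients)) {
      raw[[m]]$coefficients <- unlist(raw[[m]]$coefficients)
    }
  }
  do.call(generative_config, raw)
}

#' Feature-extraction parameters
#'
#' @param walk_lo,walk_hi Accelerometer magnitude band (g) classified as
#'   walking; the band excludes still standing below and running or impact
#'   artefacts above.
#' @param walk_min_duration Minimum duration (s) of a walking run; shorter
#'   supra-threshold bursts are discarded as posture shifts.
#' @param still_threshold Magnitude (g) below which a frame counts as still
#'   for the posture stillness ratio.
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(walk_lo = 0.15, walk_hi = 0.60,
                           walk_min_duration = 2, still_threshold = 0.05) {
  stopifnot(walk_lo <= walk_hi, walk_min_duration >= 0)
  structure(list(walk_lo = walk_lo, walk_hi = walk_hi,
                 walk_min_duration = walk_min_duration,
                 still_threshold = still_threshold),
            class = "feature_params")
}
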