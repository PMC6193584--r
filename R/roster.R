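#' Generate a shift roster with task demands
#'
#' Draws one record per shift: date class (weekday/weekend), staffing factors
#' (number of patients, patients assigned a sitter, assistant present),
#' eight patient-factor counts (patients requiring specific care
#' interventions, e.g. an insulin drip), and a composite average patient
#' load. Latent per-shift effect columns (prefixed `eff_`) carry the shift
#' random effects that the stream simulator uses so that segments of the same
#' shift share dwell, speech, movement and ambient conditions; they are part
#' of the recorded ground truth, not observed data.
#'
#' Exertion ratings are left empty; they are filled in by
#' [generate_exertion()] once segment features exist.
#'
#' @param config A [generative_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with `config$n_shifts` rows.
#' @export
generate_roster <- function(config = generative_config(), seed = config$seed) {
  validate_generative_config(config)
  set.seed(seed)
  n <- config$n_shifts
  d <- config$demands
  if (n == 0) {
    return(tibble::tibble(shift_id = character(), date_class = character()))
  }

  n_patients <- sample(d$n_patients_levels, n, replace = TRUE,
                       prob = d$n_patients_probs)
  factors <- lapply(d$factor_probs, function(p) rbinom(n, n_patients, p))
  total_interventions <- Reduce(`+`, factors)

  roster <- tibble::tibble(
    shift_id = sprintf("S%03d", seq_len(n)),
    date_class = ifelse(runif(n) < config$weekend_prob, "weekend", "weekday"),
    n_patients = n_patients,
    n_sitters = rbinom(n, n_patients, d$sitter_prob),
    assistant_present = rbinom(n, 1, d$assistant_prob),
    !!!factors,
    average_patient_load = pmax(0, total_interventions / n_patients +
                                  rnorm(n, 0, d$load_noise_sd))
  )

  # latent shift effects shared by all segments of a shift
  ls <- config$location$shift_dwell_sd
  roster$eff_dwell_patient_room <- exp(rnorm(n, 0, ls))
  roster$eff_dwell_nursing_station <- exp(rnorm(n, 0, ls))
  roster$eff_dwell_service_area <- exp(rnorm(n, 0, ls))
  roster$eff_dwell_off_main <- exp(rnorm(n, 0, ls))
  roster$eff_speech_gap <- exp(rnorm(n, 0, config$speech$shift_gap_sd))
  roster$eff_volume <- rnorm(n, 0, config$speech$shift_volume_sd)
  roster$eff_pitch <- rnorm(n, 0, config$speech$shift_pitch_sd)
  roster$eff_accel <- rnorm(n, 0, config$accel$shift_sd)
  for (cl in main_zone_classes) {
    roster[[paste0("eff_noise_", cl)]] <-
      rnorm(n, 0, config$ambient$shift_noise_sd)
    roster[[paste0("eff_temp_", cl)]] <-
      rnorm(n, 0, config$ambient$shift_temperature_sd)
  }
  roster
}

#' Task-demand column names
#'
#' The shift-level (Level 2) variables produced by [generate_roster()], in
#' the order staffing factors, patient factors, composite load.
#' @param config A [generative_config()].
#' @return Character vector of column names.
#' @export
task_demand_names <- function(config = generative_config()) {
  c("n_patients", "n_sitters", "assistant_present",
    names(config$demands$factor_probs), "average_patient_load")
}
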