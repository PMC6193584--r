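#' Burstiness of a point process
#'
#' The burstiness statistic `B = (sigma - mu) / (sigma + mu)` of the
#' inter-event times, where `mu` is the mean gap and `sigma` the sample
#' (n-1 denominator) standard deviation. `B = -1` for a perfectly periodic
#' train, `B` near 0 for Poisson-like events, and `B -> 1` for extremely
#' clumped activity.
#'
#' @param event_times Numeric vector of event times (seconds); order is
#'   irrelevant, times are sorted internally.
#' @return `B` in `[-1, 1]`, or `NA` when fewer than three events (fewer than
#'   two gaps) make the statistic undefined. The `NA` propagates as a missing
#'   feature value.
#' @examples
#' burstiness(c(0, 1, 3, 6))   # gaps 1,2,3 -> -1/3
#' burstiness(seq(0, 100, 10)) # periodic -> -1
#' @export
burstiness <- function(event_times) {
  event_times <- sort(event_times[!is.na(event_times)])
  if (length(event_times) < 3) return(NA_real_)
  gaps <- diff(event_times)
  mu <- mean(gaps)
  s <- sd(gaps)
  if (s + mu == 0) return(NA_real_)  # all events coincident
  (s - mu) / (s + mu)
}

#' Shannon entropy of location transitions
#'
#' Entropy (base 2) of the empirical distribution of consecutive
#' distinct-zone transition pairs in a location sequence. Consecutive
#' repeats of the same zone (interval fragmentation artefacts) are merged
#' before pairs are formed. Low entropy means predictable movement routes.
#'
#' @param zones Character vector: the zone sequence in time order.
#' @return Entropy in bits; 0 when the sequence contains no transition.
#' @examples
#' transition_entropy(c("A", "B", "A", "B", "A")) # 1 bit
#' transition_entropy(rep("A", 10))               # 0
#' @export
transition_entropy <- function(zones) {
  zones <- as.character(zones)
  zones <- zones[c(TRUE, zones[-1] != zones[-length(zones)])]
  if (length(zones) < 2) return(0)
  pairs <- paste(zones[-length(zones)], zones[-1], sep = "\r")
  p <- as.numeric(table(pairs))
  p <- p / sum(p)
  -sum(p * log2(p))
}

check_intervals <- function(intervals, segment_length) {
  if (!nrow(intervals)) return(invisible(intervals))
  if (any(intervals$start_s < -1e-9 |
          intervals$end_s > segment_length + 1e-9)) {
    stop("location interval outside segment bounds [0, ", segment_length, "]")
  }
  if (any(intervals$end_s < intervals$start_s)) {
    stop("location interval with end before start")
  }
  invisible(intervals)
}

#' Fraction of a segment spent in a zone class
#'
#' @param intervals Location intervals (`zone_class`, `start_s`, `end_s`).
#' @param zone_class One of [zone_classes].
#' @param segment_length Segment length in seconds.
#' @return Fraction of the segment in `[0, 1]`.
#' @export
time_in_zone_class <- function(intervals, zone_class, segment_length) {
  stopifnot(zone_class %in% zone_classes)
  check_intervals(intervals, segment_length)
  sel <- intervals$zone_class == zone_class
  sum(intervals$end_s[sel] - intervals$start_s[sel]) / segment_length
}

in_class_at <- function(t, intervals, zone_class) {
  iv <- intervals[intervals$zone_class %in% zone_class, , drop = FALSE]
  if (!nrow(iv)) return(rep(FALSE, length(t)))
  iv <- iv[order(iv$start_s), ]
  idx <- findInterval(t, iv$start_s)
  idx > 0 & t <= iv$end_s[pmax(idx, 1)]
}

#' Mean of a sensor channel conditioned on a zone class
#'
#' Averages frame values over the times the nurse occupied zones of the
#' given class. For ambient channels (which carry a `zone_class` column of
#' their own), only frames from that class's stationary sensors are used,
#' so e.g. "environmental noise in patient rooms" is patient-room sensor
#' noise during patient-room presence.
#'
#' @param frames Frame tibble with `t_s` and the channel column (ambient
#'   frames also have `zone_class`).
#' @param intervals Location intervals.
#' @param channel Channel column name.
#' @param zone_class Zone class to condition on.
#' @return Mean channel value, or `NA` when no qualifying frames exist.
#' @export
zone_conditioned_mean <- function(frames, intervals, channel, zone_class) {
  if (!channel %in% names(frames)) {
    stop("unknown channel: ", channel)
  }
  stopifnot(zone_class %in% zone_classes)
  if ("zone_class" %in% names(frames)) {
    frames <- frames[frames$zone_class == zone_class, , drop = FALSE]
  }
  sel <- in_class_at(frames$t_s, intervals, zone_class)
  v <- frames[[channel]][sel]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

speech_episodes <- function(speech) {
  r <- rle(speech$speaking)
  ends <- cumsum(r$lengths)
  starts_idx <- c(1, head(ends, -1) + 1)
  on <- which(r$values)
  tibble::tibble(start_s = speech$t_s[starts_idx[on]],
                 end_s = speech$t_s[ends[on]])
}

#' Speaking features for one segment
#'
#' Speaking episodes are maximal runs of speaking frames. Returns the total
#' speaking time fraction, the fraction per zone class (share of the whole
#' segment spent speaking while in that class), mean volume while speaking
#' overall and per class, mean pitch, the number of episodes, and the
#' burstiness of speaking (the [burstiness()] of episode start times).
#'
#' @param speech Speech frames (`t_s`, `speaking`, `volume_db`, `pitch_hz`).
#' @param intervals Location intervals.
#' @return Named list of speaking features; missing sentinels (`NA`)
#'   propagate where undefined (e.g. no speaking at all).
#' @export
speaking_features <- function(speech, intervals) {
  speech <- speech[order(speech$t_s), ]
  n <- nrow(speech)
  out <- list()
  out$time_speaking <- if (n) mean(speech$speaking) else NA_real_
  for (cl in zone_classes) {
    key <- if (cl == "off_main") "time_speaking_outside_main" else
      paste0("time_speaking_", cl, "s")
    sel <- in_class_at(speech$t_s, intervals, cl)
    out[[key]] <- if (n) mean(speech$speaking & sel) else NA_real_
  }
  spk <- speech[speech$speaking, , drop = FALSE]
  out$volume_speaking <- if (nrow(spk)) mean(spk$volume_db, na.rm = TRUE) else
    NA_real_
  ns_sel <- in_class_at(spk$t_s, intervals, "nursing_station")
  out$volume_speaking_nursing_stations <-
    if (any(ns_sel)) mean(spk$volume_db[ns_sel], na.rm = TRUE) else NA_real_
  out$pitch_speaking <- if (nrow(spk)) mean(spk$pitch_hz, na.rm = TRUE) else
    NA_real_
  ep <- speech_episodes(speech)
  out$n_speech_episodes <- nrow(ep)
  out$burstiness_speaking <- burstiness(ep$start_s)
  out
}

walking_frames <- function(accel, params) {
  accel <- accel[order(accel$t_s), ]
  dt <- if (nrow(accel) > 1) stats::median(diff(accel$t_s)) else 1
  walk <- accel$magnitude_g >= params$walk_lo & accel$magnitude_g < params$walk_hi
  r <- rle(walk)
  too_short <- r$values & (r$lengths * dt) < params$walk_min_duration
  r$values[too_short] <- FALSE
  list(times = accel$t_s[inverse.rle(r)], dt = dt)
}

#' Walking time within a zone class
#'
#' Frames whose accelerometer magnitude falls in the configured walking band
#' `[walk_lo, walk_hi)` are classified as walking; contiguous walking runs
#' shorter than `walk_min_duration` are discarded; the surviving walking
#' seconds spent inside zones of the class are summed.
#'
#' @param accel Accelerometer frames (`t_s`, `magnitude_g`).
#' @param intervals Location intervals.
#' @param zone_class Zone class (or `NULL` for the whole segment).
#' @param params A [feature_params()].
#' @return Walking time in seconds.
#' @export
walking_time <- function(accel, intervals, zone_class = NULL,
                         params = feature_params()) {
  wf <- walking_frames(accel, params)
  t <- wf$times
  if (!is.null(zone_class)) t <- t[in_class_at(t, intervals, zone_class)]
  length(t) * wf$dt
}

#' Feature registry
#'
#' The catalogue of per-segment work-process features this package extracts,
#' organised into the seven sensor categories (location, accelerometer,
#' environmental noise, speaking, posture, walking, temperature). Each entry
#' has an internal `name`, the human-readable `label` used in reports (for
#' the thirteen modelled features these use the wording reports conventionally print),
#' its `category`, and whether it is one of the modelled headline features.
#' The registry is data-driven so the catalogue can be extended without code
#' changes.
#'
#' @return A tibble with columns `name`, `label`, `category`, `modelled`.
#' @export
feature_registry <- function() {
  reg <- tibble::tribble(
    ~name, ~label, ~category, ~modelled,
    "time_patient_rooms", "Time in patient rooms", "location", FALSE,
    "time_nursing_stations", "Time at nursing stations", "location", TRUE,
    "time_service_areas", "Time in service areas", "location", FALSE,
    "time_outside_main", "Time outside of main work areas", "location", TRUE,
    "n_transitions", "Number of zone transitions", "location", FALSE,
    "mean_dwell_s", "Mean dwell time per location (s)", "location", FALSE,
    "entropy_transitions", "Entropy of transitions", "location", TRUE,
    "burstiness_transitions", "Burstiness of transitions", "location", TRUE,
    "activity_overall", "Activity level overall", "accelerometer", FALSE,
    "activity_patient_rooms", "Activity level in patient rooms",
    "accelerometer", FALSE,
    "activity_nursing_stations", "Activity level at nursing stations",
    "accelerometer", FALSE,
    "activity_service_areas", "Activity level in service areas",
    "accelerometer", FALSE,
    "activity_outside_main", "Activity level outside of main work areas",
    "accelerometer", TRUE,
    "noise_patient_rooms", "Environmental noise in patient rooms",
    "environmental_noise", TRUE,
    "noise_nursing_stations", "Environmental noise at nursing stations",
    "environmental_noise", FALSE,
    "noise_service_areas", "Environmental noise in service areas",
    "environmental_noise", TRUE,
    "time_speaking", "Time speaking", "speaking", FALSE,
    "time_speaking_patient_rooms", "Time speaking in patient rooms",
    "speaking", FALSE,
    "time_speaking_nursing_stations", "Time speaking at nursing stations",
    "speaking", FALSE,
    "time_speaking_service_areas", "Time speaking in service areas",
    "speaking", FALSE,
    "time_speaking_outside_main", "Time speaking outside of main work areas",
    "speaking", TRUE,
    "volume_speaking", "Volume while speaking", "speaking", FALSE,
    "volume_speaking_nursing_stations",
    "Volume while speaking at nursing stations", "speaking", TRUE,
    "pitch_speaking", "Pitch while speaking", "speaking", FALSE,
    "n_speech_episodes", "Number of speech episodes", "speaking", FALSE,
    "burstiness_speaking", "Burstiness of speaking", "speaking", TRUE,
    "posture_still_ratio", "Posture stillness ratio", "posture", FALSE,
    "walking_time_s", "Time walking (s)", "walking", FALSE,
    "time_walking_patient_rooms", "Time walking in patient rooms",
    "walking", TRUE,
    "burstiness_walking", "Burstiness of walking", "walking", FALSE,
    "temp_patient_rooms", "Temperature in patient rooms", "temperature",
    FALSE,
    "temp_nursing_stations", "Temperature at nursing stations", "temperature",
    FALSE,
    "temp_service_areas", "Temperature in service areas", "temperature", TRUE
  )
  reg
}

#' Extract the full per-segment feature vector
#'
#' Computes every feature in the [feature_registry()] from one segment's
#' event streams. Frames are sorted by time first, so the result is invariant
#' to frame ordering. Time features are fractions of the segment except
#' walking times, which are in seconds.
#'
#' @param streams An `event_streams` object (see
#'   [simulate_segment_streams()]).
#' @param map A [unit_map()] (currently unused beyond validation, kept for
#'   extension with per-zone features).
#' @param params A [feature_params()].
#' @return A one-row tibble, one column per registry feature.
#' @export
extract_all <- function(streams, map = default_unit_map(),
                        params = feature_params()) {
  problems <- validate_streams(streams)
  if (length(problems)) {
    stop("malformed event streams: ", paste(problems, collapse = "; "))
  }
  len <- streams$segment_length
  iv <- streams$intervals[order(streams$intervals$start_s), ]
  speech <- streams$speech[order(streams$speech$t_s), ]
  accel <- streams$accel[order(streams$accel$t_s), ]
  ambient <- streams$ambient[order(streams$ambient$t_s), ]

  out <- list()
  out$time_patient_rooms <- time_in_zone_class(iv, "patient_room", len)
  out$time_nursing_stations <- time_in_zone_class(iv, "nursing_station", len)
  out$time_service_areas <- time_in_zone_class(iv, "service_area", len)
  out$time_outside_main <- time_in_zone_class(iv, "off_main", len)

  # merged distinct-zone runs define transitions
  merged <- iv$zone_id[c(TRUE, iv$zone_id[-1] != iv$zone_id[-nrow(iv)])]
  trans_times <- iv$start_s[c(FALSE, iv$zone_id[-1] != iv$zone_id[-nrow(iv)])]
  out$n_transitions <- length(trans_times)
  out$mean_dwell_s <- len / max(length(merged), 1)
  out$entropy_transitions <- transition_entropy(iv$zone_id)
  out$burstiness_transitions <- burstiness(trans_times)

  out$activity_overall <- mean(accel$magnitude_g)
  out$activity_patient_rooms <-
    zone_conditioned_mean(accel, iv, "magnitude_g", "patient_room")
  out$activity_nursing_stations <-
    zone_conditioned_mean(accel, iv, "magnitude_g", "nursing_station")
  out$activity_service_areas <-
    zone_conditioned_mean(accel, iv, "magnitude_g", "service_area")
  out$activity_outside_main <-
    zone_conditioned_mean(accel, iv, "magnitude_g", "off_main")

  out$noise_patient_rooms <-
    zone_conditioned_mean(ambient, iv, "noise_db", "patient_room")
  out$noise_nursing_stations <-
    zone_conditioned_mean(ambient, iv, "noise_db", "nursing_station")
  out$noise_service_areas <-
    zone_conditioned_mean(ambient, iv, "noise_db", "service_area")
  out$temp_patient_rooms <-
    zone_conditioned_mean(ambient, iv, "temperature_c", "patient_room")
  out$temp_nursing_stations <-
    zone_conditioned_mean(ambient, iv, "temperature_c", "nursing_station")
  out$temp_service_areas <-
    zone_conditioned_mean(ambient, iv, "temperature_c", "service_area")

  out <- c(out, speaking_features(speech, iv))

  out$posture_still_ratio <- mean(accel$magnitude_g < params$still_threshold)
  out$walking_time_s <- walking_time(accel, iv, NULL, params)
  out$time_walking_patient_rooms <-
    walking_time(accel, iv, "patient_room", params)
  wf <- walking_frames(accel, params)
  run_starts <- wf$times[c(TRUE, diff(wf$times) > wf$dt * 1.5)]
  out$burstiness_walking <- burstiness(run_starts)

  reg <- feature_registry()
  tibble::as_tibble(out)[, reg$name]
}

#' Assemble a feature matrix from per-segment streams
#'
#' @param segments A list with elements `shift_id`, `segment_index`, and
#'   `streams` per entry, or a tibble with a `streams` list-column.
#' @param map A [unit_map()].
#' @param params A [feature_params()].
#' @return A tibble keyed by (`shift_id`, `segment_index`) with one column
#'   per feature.
#' @export
build_feature_matrix <- function(segments, map = default_unit_map(),
                                 params = feature_params()) {
  rows <- purrr::map(segments, function(seg) {
    dplyr::bind_cols(
      tibble::tibble(shift_id = seg$shift_id,
                     segment_index = seg$segment_index),
      extract_all(seg$streams, map, params)
    )
  })
  dplyr::bind_rows(rows)
}

#' Grand-mean centre (and optionally scale) feature columns
#'
#' Centres every feature column of a feature matrix on its grand mean and,
#' if `scale = TRUE`, divides by its standard deviation. Key columns
#' (`shift_id`, `segment_index`) and any non-numeric columns are left
#' untouched. The centring constants are stored as attributes `center` and
#' `scale` so values can be mapped back to original units.
#'
#' @param matrix A feature-matrix tibble.
#' @param scale Also divide by the column standard deviation.
#' @param cols Columns to standardise; defaults to all numeric non-key
#'   columns.
#' @return The standardised tibble with `center`/`scale` attributes.
#' @export
standardize <- function(matrix, scale = TRUE, cols = NULL) {
  keys <- intersect(c("shift_id", "segment_index"), names(matrix))
  if (is.null(cols)) {
    cols <- setdiff(names(matrix)[vapply(matrix, is.numeric, logical(1))],
                    keys)
  }
  centers <- vapply(matrix[cols], function(x) mean(x, na.rm = TRUE),
                    numeric(1))
  scales <- rep(1, length(cols))
  names(scales) <- cols
  if (scale) {
    scales <- vapply(matrix[cols], function(x) sd(x, na.rm = TRUE),
                     numeric(1))
    zero <- names(scales)[!is.na(scales) & scales == 0]
    if (length(zero)) {
      stop("cannot scale zero-variance column(s): ",
           paste(zero, collapse = ", "))
    }
  }
  for (j in cols) {
    matrix[[j]] <- (matrix[[j]] - centers[[j]]) / scales[[j]]
  }
  attr(matrix, "center") <- centers
  attr(matrix, "scale") <- scales
  matrix
}
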