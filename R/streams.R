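rpareto <- function(n, mean, shape) {
  xm <- mean * (shape - 1) / shape
  xm * runif(n)^(-1 / shape)
}

sample_gaps <- function(n, mean, dist, shape) {
  switch(dist,
         exponential = rexp(n, 1 / mean),
         pareto = rpareto(n, mean, shape))
}

#' Simulate raw sensor event streams for one shift segment
#'
#' Produces the four raw streams a badge system yields for a four-hour
#' segment:
#' \describe{
#'   \item{intervals}{resolved location intervals from a semi-Markov chain
#'     over zones: class-level transition matrix, gamma dwell times whose
#'     means are modulated by the shift's latent dwell multipliers; the
#'     intervals tile `[0, segment_length]` without overlap.}
#'   \item{speech}{frame series of speaking flag, volume (dB) and pitch (Hz)
#'     from a two-state on/off renewal process; inter-episode gaps are
#'     exponential (Poisson-like speaking) or Pareto (bursty speaking).}
#'   \item{accel}{frame series of accelerometer magnitude (g) around
#'     zone-class baselines, with walking bouts following each zone change
#'     and occasional in-room activity bouts.}
#'   \item{ambient}{stationary-sensor frames of noise (dB) and temperature
#'     (C) per instrumented zone, around class baselines plus the shift's
#'     ambient offsets.}
#' }
#'
#' @param shift A single roster row from [generate_roster()] (carries the
#'   latent `eff_` shift effects).
#' @param map A [unit_map()].
#' @param config A [generative_config()].
#' @param seed Integer seed.
#' @return A list of class `event_streams`.
#' @export
simulate_segment_streams <- function(shift, map = default_unit_map(),
                                     config = generative_config(),
                                     seed = config$seed) {
  stopifnot(inherits(map, "unit_map"), nrow(shift) == 1)
  validate_generative_config(config)
  set.seed(seed)
  len <- config$segment_length
  loc <- config$location

  dwell_mult <- c(
    patient_room = shift$eff_dwell_patient_room,
    nursing_station = shift$eff_dwell_nursing_station,
    service_area = shift$eff_dwell_service_area,
    off_main = shift$eff_dwell_off_main
  )
  dwell_mean <- loc$dwell_mean[zone_classes] * dwell_mult[zone_classes]

  zones_by_class <- split(map$zone_id, map$zone_class)

  pick_zone <- function(class, avoid = NULL) {
    z <- zones_by_class[[class]]
    if (!is.null(avoid) && length(z) > 1) z <- setdiff(z, avoid)
    if (length(z) == 1) z else sample(z, 1)
  }

  # semi-Markov location process
  n_guess <- max(16L, ceiling(3 * len / min(dwell_mean)))
  cls <- character(n_guess); zn <- character(n_guess); dw <- numeric(n_guess)
  cur_class <- sample(zone_classes, 1, prob = dwell_mean)
  cur_zone <- pick_zone(cur_class)
  t <- 0; i <- 0
  while (t < len) {
    i <- i + 1
    if (i > length(cls)) {
      cls <- c(cls, character(n_guess)); zn <- c(zn, character(n_guess))
      dw <- c(dw, numeric(n_guess))
    }
    d <- rgamma(1, shape = loc$dwell_shape,
                scale = dwell_mean[[cur_class]] / loc$dwell_shape)
    cls[i] <- cur_class; zn[i] <- cur_zone; dw[i] <- d
    t <- t + d
    nxt_class <- sample(zone_classes, 1, prob = loc$transition[cur_class, ])
    cur_zone <- pick_zone(nxt_class,
                          avoid = if (nxt_class == cur_class) cur_zone)
    cur_class <- nxt_class
  }
  cls <- cls[seq_len(i)]; zn <- zn[seq_len(i)]; dw <- dw[seq_len(i)]
  ends <- pmin(cumsum(dw), len)
  starts <- c(0, head(ends, -1))
  intervals <- tibble::tibble(zone_id = zn, zone_class = cls,
                              start_s = starts, end_s = ends)
  intervals <- intervals[intervals$end_s > intervals$start_s, ]

  # speech renewal process (gap, episode, gap, ...)
  sp <- config$speech
  gap_mean <- sp$gap_mean * shift$eff_speech_gap
  n_ep_guess <- max(16L, ceiling(3 * len / (gap_mean + sp$episode_mean)))
  gaps <- sample_gaps(n_ep_guess, gap_mean, sp$gap_dist, sp$pareto_shape)
  eps <- rexp(n_ep_guess, 1 / sp$episode_mean)
  while (sum(gaps + eps) < len) {
    gaps <- c(gaps, sample_gaps(n_ep_guess, gap_mean, sp$gap_dist,
                                sp$pareto_shape))
    eps <- c(eps, rexp(n_ep_guess, 1 / sp$episode_mean))
  }
  ep_start <- cumsum(gaps) + c(0, head(cumsum(eps), -1))
  ep_end <- ep_start + eps
  keep <- ep_start < len
  ep_start <- ep_start[keep]; ep_end <- pmin(ep_end[keep], len)

  dt <- 1 / config$frame_rate
  t_frame <- seq(dt / 2, len, by = dt)
  in_episode <- function(t) {
    idx <- findInterval(t, ep_start)
    idx > 0 & t < ep_end[pmax(idx, 1)]
  }
  speaking <- in_episode(t_frame)
  seg_volume <- rnorm(1, 0, sp$segment_volume_sd)
  seg_pitch <- rnorm(1, 0, sp$segment_pitch_sd)
  volume <- ifelse(speaking,
                   sp$volume_mean + shift$eff_volume + seg_volume +
                     rnorm(length(t_frame), 0, sp$volume_sd), NA_real_)
  pitch <- ifelse(speaking,
                  sp$pitch_mean + shift$eff_pitch + seg_pitch +
                    rnorm(length(t_frame), 0, sp$pitch_sd), NA_real_)
  speech <- tibble::tibble(t_s = t_frame, speaking = speaking,
                           volume_db = volume, pitch_hz = pitch)

  # accelerometer magnitudes
  ac <- config$accel
  frame_class <- intervals$zone_class[
    findInterval(t_frame, intervals$start_s, rightmost.closed = TRUE)]
  mag <- ac$baseline[frame_class] + shift$eff_accel +
    rnorm(length(t_frame), 0, ac$frame_sd)
  walk_starts <- intervals$start_s[-1]
  if (length(walk_starts)) {
    walk_durs <- runif(length(walk_starts), ac$walk_duration[1],
                       ac$walk_duration[2])
    for (b in seq_along(walk_starts)) {
      idx <- t_frame >= walk_starts[b] & t_frame < walk_starts[b] + walk_durs[b]
      mag[idx] <- rnorm(sum(idx), ac$walk_level, ac$walk_sd)
    }
  }
  n_bouts <- rpois(1, ac$room_bout_rate * len)
  if (n_bouts > 0) {
    bout_t <- runif(n_bouts, 0, len)
    bout_d <- runif(n_bouts, ac$room_bout_duration[1], ac$room_bout_duration[2])
    for (b in seq_len(n_bouts)) {
      idx <- t_frame >= bout_t[b] & t_frame < bout_t[b] + bout_d[b]
      mag[idx] <- rnorm(sum(idx), ac$walk_level, ac$walk_sd)
    }
  }
  accel <- tibble::tibble(t_s = t_frame, magnitude_g = pmax(mag, 0))

  # ambient frames from stationary sensors
  am <- config$ambient
  t_amb <- seq(1 / config$ambient_rate / 2, len, by = 1 / config$ambient_rate)
  inst <- map[map$n_sensors > 0, ]
  ambient <- tidyr::expand_grid(zone_id = inst$zone_id, t_s = t_amb)
  ambient$zone_class <- zone_class_of(map)[ambient$zone_id]
  n_amb <- nrow(ambient)
  eff_noise <- setNames(as.numeric(shift[1, paste0("eff_noise_",
                                                   main_zone_classes)]),
                        main_zone_classes)
  eff_temp <- setNames(as.numeric(shift[1, paste0("eff_temp_",
                                                  main_zone_classes)]),
                       main_zone_classes)
  seg_noise <- setNames(rnorm(3, 0, am$segment_noise_sd), main_zone_classes)
  seg_temp <- setNames(rnorm(3, 0, am$segment_temperature_sd),
                       main_zone_classes)
  noise_eff <- eff_noise[ambient$zone_class] + seg_noise[ambient$zone_class]
  temp_eff <- eff_temp[ambient$zone_class] + seg_temp[ambient$zone_class]
  ambient$noise_db <- am$noise[ambient$zone_class] + noise_eff +
    rnorm(n_amb, 0, am$noise_sd)
  ambient$temperature_c <- am$temperature[ambient$zone_class] + temp_eff +
    rnorm(n_amb, 0, am$temperature_sd)
  ambient <- ambient[, c("t_s", "zone_id", "zone_class", "noise_db",
                         "temperature_c")]

  structure(list(intervals = intervals, speech = speech, accel = accel,
                 ambient = ambient, segment_length = len,
                 frame_rate = config$frame_rate),
            class = "event_streams")
}

#' Validate an event-streams object
#'
#' Checks the structural invariants: interval and frame times within
#' `[0, segment_length]`, non-overlapping intervals that tile the segment,
#' and a logical speaking flag. Returns a character vector of problems
#' (empty when valid).
#'
#' @param streams An `event_streams` object.
#' @return Invisibly, a character vector of validation messages.
#' @export
validate_streams <- function(streams) {
  msgs <- character()
  iv <- streams$intervals
  len <- streams$segment_length
  if (nrow(iv)) {
    iv <- iv[order(iv$start_s), ]
    if (any(iv$start_s < 0 | iv$end_s > len + 1e-9)) {
      msgs <- c(msgs, "location intervals outside segment bounds")
    }
    if (any(iv$end_s < iv$start_s)) {
      msgs <- c(msgs, "location intervals with negative duration")
    }
    if (nrow(iv) > 1 &&
        any(iv$start_s[-1] < iv$end_s[-nrow(iv)] - 1e-9)) {
      msgs <- c(msgs, "overlapping location intervals")
    }
  }
  for (nm in c("speech", "accel", "ambient")) {
    fr <- streams[[nm]]
    if (nrow(fr) && any(fr$t_s < 0 | fr$t_s > len)) {
      msgs <- c(msgs, paste(nm, "frames outside segment bounds"))
    }
  }
  if (nrow(streams$speech) && !is.logical(streams$speech$speaking)) {
    msgs <- c(msgs, "speaking flag is not logical")
  }
  invisible(msgs)
}
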