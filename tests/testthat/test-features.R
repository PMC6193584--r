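test_that("burstiness matches its defining formula on canonical cases", {
  expect_equal(burstiness(seq(0, 90, by = 10)), -1)          # periodic
  expect_equal(burstiness(c(0, 1, 3, 6)), -1 / 3)            # gaps 1,2,3
  # gaps (1, 3 + 2*sqrt(2)) have sample sd equal to their mean -> B = 0
  expect_equal(burstiness(c(0, 1, 4 + 2 * sqrt(2))), 0, tolerance = 1e-12)
  expect_true(is.na(burstiness(c(0, 5))))                    # < 3 events
  expect_true(is.na(burstiness(numeric())))
})

test_that("burstiness equals brute-force evaluation and stays in [-1, 1]", {
  set.seed(42)
  for (i in 1:500) {
    k <- sample(3:40, 1)
    times <- cumsum(c(0, rexp(k - 1, rate = runif(1, 0.01, 10))^
                        runif(1, 0.5, 2)))
    b <- burstiness(times)
    expect_equal(b, brute_burstiness(times))
    expect_gte(b, -1)
    expect_lte(b, 1)
  }
})

test_that("transition entropy handles degenerate, alternating and cyclic routes", {
  expect_equal(transition_entropy(rep("A", 7)), 0)
  expect_equal(transition_entropy(c("A", "B", "A", "B", "A")), 1)
  expect_equal(transition_entropy(c("A", "B", "C", "A", "B", "C", "A")),
               log2(3))
  # interval fragmentation: self-repeats merged before pairing
  expect_equal(transition_entropy(c("A", "A", "B", "B", "A", "A")), 1)
  expect_equal(transition_entropy(character()), 0)
})

test_that("transition entropy equals brute enumeration and respects its bound", {
  set.seed(7)
  for (i in 1:500) {
    zones <- sample(LETTERS[1:sample(2:6, 1)], sample(2:50, 1),
                    replace = TRUE)
    h <- transition_entropy(zones)
    expect_equal(h, brute_entropy(zones))
    merged <- rle(zones)$values
    n_pairs <- length(unique(paste(merged[-length(merged)], merged[-1])))
    expect_gte(h, 0)
    expect_lte(h, log2(max(n_pairs, 1)) + 1e-12)
  }
})

test_that("time in zone class is an exact duration fraction", {
  iv <- tibble::tibble(zone_id = "pr01", zone_class = "patient_room",
                       start_s = 0, end_s = 14400)
  expect_equal(time_in_zone_class(iv, "patient_room", 14400), 1.0)
  expect_equal(time_in_zone_class(iv, "service_area", 14400), 0.0)
  iv2 <- tibble::tibble(zone_id = c("sa_supply", "pr01"),
                        zone_class = c("service_area", "patient_room"),
                        start_s = c(0, 3600), end_s = c(3600, 14400))
  expect_equal(time_in_zone_class(iv2, "service_area", 14400), 0.25)
  bad <- tibble::tibble(zone_id = "pr01", zone_class = "patient_room",
                        start_s = -5, end_s = 100)
  expect_error(time_in_zone_class(bad, "patient_room", 14400), "bounds")
})

test_that("zone-conditioned means average the qualifying frames only", {
  iv <- tibble::tibble(zone_id = c("pr01", "ns1"),
                       zone_class = c("patient_room", "nursing_station"),
                       start_s = c(0, 50), end_s = c(50, 100))
  frames <- tibble::tibble(t_s = seq(0.5, 99.5, by = 1),
                           magnitude_g = 0.25)
  expect_equal(zone_conditioned_mean(frames, iv, "magnitude_g",
                                     "patient_room"), 0.25)
  # ambient: half the qualifying frames at 40 dB, half at 60 dB -> 50 dB
  amb <- tibble::tibble(t_s = rep(seq(0.5, 49.5, 1), 2),
                        zone_class = "patient_room",
                        zone_id = "pr01",
                        noise_db = rep(c(40, 60), each = 50))
  expect_equal(zone_conditioned_mean(amb, iv, "noise_db", "patient_room"), 50)
  expect_true(is.na(zone_conditioned_mean(frames, iv, "magnitude_g",
                                          "service_area")))
  expect_error(zone_conditioned_mean(frames, iv, "no_such", "patient_room"),
               "channel")
})

test_that("speaking features count episodes and fractions correctly", {
  # 100 frames; speaking for frames 26-75 (one long episode), all at ns
  iv <- tibble::tibble(zone_id = "ns1", zone_class = "nursing_station",
                       start_s = 0, end_s = 100)
  sp <- tibble::tibble(t_s = seq(0.5, 99.5, 1),
                       speaking = dplyr::between(seq(0.5, 99.5, 1), 25, 75),
                       volume_db = ifelse(dplyr::between(seq(0.5, 99.5, 1),
                                                         25, 75), 62, NA),
                       pitch_hz = 180)
  f <- speaking_features(sp, iv)
  expect_equal(f$time_speaking, 0.5, tolerance = 0.02)
  expect_equal(f$time_speaking_nursing_stations, f$time_speaking)
  expect_equal(f$time_speaking_patient_rooms, 0)
  expect_equal(f$volume_speaking_nursing_stations, 62)
  expect_equal(f$n_speech_episodes, 1)
  expect_true(is.na(f$burstiness_speaking))  # one episode: undefined

  # periodic episode starts give B = -1
  t <- seq(0.5, 199.5, 1)
  sp2 <- tibble::tibble(t_s = t, speaking = (floor(t) %% 20) < 5,
                        volume_db = 60, pitch_hz = 150)
  expect_equal(speaking_features(sp2, iv)$burstiness_speaking, -1)

  # silence: sentinels propagate
  sp3 <- tibble::tibble(t_s = t, speaking = FALSE, volume_db = NA_real_,
                        pitch_hz = NA_real_)
  f3 <- speaking_features(sp3, iv)
  expect_equal(f3$time_speaking, 0)
  expect_true(is.na(f3$volume_speaking))
  expect_true(is.na(f3$burstiness_speaking))
})

test_that("walking time applies the band, the minimum duration and the class", {
  iv <- tibble::tibble(zone_id = c("pr01", "off_main"),
                       zone_class = c("patient_room", "off_main"),
                       start_s = c(0, 300), end_s = c(300, 600))
  t <- seq(0.5, 599.5, 1)
  still <- tibble::tibble(t_s = t, magnitude_g = 0.05)
  expect_equal(walking_time(still, iv, "patient_room"), 0)

  mag <- rep(0.05, 600)
  mag[101:220] <- 0.3                       # single 120 s walking run in room
  acc <- tibble::tibble(t_s = t, magnitude_g = mag)
  expect_equal(walking_time(acc, iv, "patient_room"), 120)
  expect_equal(walking_time(acc, iv, "off_main"), 0)

  # degenerate band: everything is walking
  loose <- feature_params(walk_lo = 0, walk_hi = Inf, walk_min_duration = 0)
  expect_equal(walking_time(still, iv, "patient_room", loose), 300)

  # runs shorter than the minimum duration are discarded
  mag2 <- rep(0.05, 600); mag2[50] <- 0.3
  acc2 <- tibble::tibble(t_s = t, magnitude_g = mag2)
  expect_equal(walking_time(acc2, iv, "patient_room"), 0)
})

test_that("extract_all satisfies range invariants and is order-invariant", {
  cfg <- generative_config(n_shifts = 2)
  ros <- generate_roster(cfg, seed = 5)
  st <- simulate_segment_streams(ros[1, ], config = cfg, seed = 6)
  f <- extract_all(st)

  fracs <- c(f$time_patient_rooms, f$time_nursing_stations,
             f$time_service_areas, f$time_outside_main)
  expect_equal(sum(fracs), 1, tolerance = 1e-9)
  expect_true(all(fracs >= 0 & fracs <= 1))
  for (b in c(f$burstiness_speaking, f$burstiness_transitions)) {
    if (!is.na(b)) expect_true(b >= -1 && b <= 1)
  }
  expect_gte(f$entropy_transitions, 0)
  expect_true(all(names(f) == feature_registry()$name))

  shuffled <- st
  set.seed(8)
  shuffled$speech <- st$speech[sample(nrow(st$speech)), ]
  shuffled$accel <- st$accel[sample(nrow(st$accel)), ]
  shuffled$ambient <- st$ambient[sample(nrow(st$ambient)), ]
  expect_equal(extract_all(shuffled), f)
})

test_that("a silent single-room segment yields the degenerate feature vector", {
  len <- 14400
  t <- seq(0.5, len, 1)
  streams <- structure(list(
    intervals = tibble::tibble(zone_id = "pr01", zone_class = "patient_room",
                               start_s = 0, end_s = len),
    speech = tibble::tibble(t_s = t, speaking = FALSE, volume_db = NA_real_,
                            pitch_hz = NA_real_),
    accel = tibble::tibble(t_s = t, magnitude_g = 0.02),
    ambient = tibble::tibble(t_s = numeric(), zone_id = character(),
                             zone_class = character(), noise_db = numeric(),
                             temperature_c = numeric()),
    segment_length = len, frame_rate = 1), class = "event_streams")
  f <- extract_all(streams)
  expect_equal(c(f$time_patient_rooms, f$time_nursing_stations,
                 f$time_service_areas, f$time_outside_main), c(1, 0, 0, 0))
  expect_equal(f$entropy_transitions, 0)
  expect_true(is.na(f$burstiness_speaking))
  expect_true(is.na(f$volume_speaking))
  expect_equal(f$walking_time_s, 0)
})

test_that("standardisation centres, scales, and reports zero-variance columns", {
  m <- tibble::tibble(shift_id = c("a", "a", "b"), segment_index = 1:3,
                      f1 = c(1, 2, 3), f2 = c(5, 5, 8))
  ctr <- standardize(m, scale = FALSE)
  expect_equal(mean(ctr$f1), 0, tolerance = 1e-12)
  expect_equal(mean(ctr$f2), 0, tolerance = 1e-12)
  expect_identical(ctr$shift_id, m$shift_id)

  sc <- standardize(m, scale = TRUE)
  expect_equal(sc$f1, c(-1, 0, 1))

  # idempotent on centred input
  ctr2 <- standardize(ctr, scale = FALSE)
  expect_equal(ctr2$f1, ctr$f1)

  m$flat <- 1
  expect_error(standardize(m, scale = TRUE), "flat")
})
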