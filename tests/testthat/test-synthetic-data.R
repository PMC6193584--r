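test_that("roster generation is reproducible, sized, and validated", {
  cfg <- generative_config(n_shifts = 35)
  r1 <- generate_roster(cfg, seed = 11)
  r2 <- generate_roster(cfg, seed = 11)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 35)
  expect_true(all(r1$n_patients >= r1$patients_on_insulin_drip))
  expect_true(all(r1$average_patient_load >= 0))
  expect_equal(nrow(generate_roster(generative_config(n_shifts = 0))), 0)
  expect_error(generative_config(dropout = 1.5), "dropout")
  expect_error(generative_config(me_model = list(var_e = -1)), "variance")
})

test_that("rating dropout is calibrated to about 89 rated segments per study", {
  cfg <- generative_config()
  rated <- vapply(1:5, function(s) {
    study <- simulate_study(cfg, seed = s, use_streams = FALSE)
    nrow(study$analysis_table)
  }, numeric(1))
  # E[rated] = 105 * (1 - 16/105) = 89; binomial sd about 3.7 per study
  expect_lt(abs(mean(rated) - 89), 6)
})

test_that("location intervals tile the segment without overlap", {
  cfg <- generative_config(n_shifts = 1)
  ros <- generate_roster(cfg, seed = 3)
  for (s in 1:3) {
    st <- simulate_segment_streams(ros[1, ], config = cfg, seed = s)
    iv <- st$intervals
    expect_equal(iv$start_s[1], 0)
    expect_equal(iv$end_s[nrow(iv)], cfg$segment_length)
    expect_equal(iv$start_s[-1], iv$end_s[-nrow(iv)])
    expect_length(validate_streams(st), 0)
  }
})

test_that("doubling dwell scales leaves the time fractions a partition", {
  cfg <- generative_config(n_shifts = 1)
  cfg2 <- generative_config(
    n_shifts = 1,
    location = list(dwell_mean = 2 * generative_config()$location$dwell_mean))
  ros <- generate_roster(cfg, seed = 4)
  for (cc in list(cfg, cfg2)) {
    f <- extract_all(simulate_segment_streams(ros[1, ], config = cc, seed = 9))
    expect_equal(f$time_patient_rooms + f$time_nursing_stations +
                   f$time_service_areas + f$time_outside_main, 1,
                 tolerance = 1e-9)
  }
})

test_that("the speech gap distribution controls downstream burstiness", {
  ros <- generate_roster(generative_config(n_shifts = 1), seed = 2)
  b_of <- function(dist, seed) {
    cfg <- generative_config(n_shifts = 1, speech = list(gap_dist = dist))
    st <- simulate_segment_streams(ros[1, ], config = cfg, seed = seed)
    extract_all(st)$burstiness_speaking
  }
  b_pareto <- vapply(1:10, function(s) b_of("pareto", s), numeric(1))
  b_exp <- vapply(1:10, function(s) b_of("exponential", s), numeric(1))
  expect_gt(median(b_pareto), 0)
  expect_lt(abs(median(b_exp)), 0.12)       # Poisson-like speaking: B near 0
  expect_gt(median(b_pareto), median(b_exp))
})

test_that("exertion ratings follow the configured mixed model", {
  cfg <- generative_config(n_shifts = 30, dropout = 0)
  feats <- simulate_features(cfg, seed = 13)
  ros <- generate_roster(cfg, seed = 13)

  # no noise at all: ratings are a deterministic function of the features
  det_cfg <- generative_config(
    n_shifts = 30, dropout = 0,
    me_model = list(var_u0 = 0, var_e = 0, var_u1 = 0),
    pe_model = list(var_u0 = 0, var_e = 0, var_u1 = 0))
  r1 <- generate_exertion(ros, feats, det_cfg, seed = 1)
  r2 <- generate_exertion(ros, feats, det_cfg, seed = 999)
  expect_identical(r1$me, r2$me)
  expect_identical(r1$pe, r2$pe)
  expect_true(all(r1$me >= 6 & r1$me <= 20))

  # equal variance components put half the latent variance between shifts
  null_cfg <- generative_config(
    n_shifts = 30, dropout = 0,
    me_model = list(coefficients = numeric(), var_u0 = 0.5, var_e = 0.5,
                    var_u1 = 0))
  r3 <- generate_exertion(ros, feats, null_cfg, seed = 21)
  truth <- attr(r3, "truth")
  est <- anova_ml(truth$me$latent, r3$shift_id)
  expect_equal(unname(est["var_u0"] / sum(est)), 0.5, tolerance = 0.2)

  # a model term that is neither a feature nor a task demand is a schema error
  bad_cfg <- generative_config(me_model = list(
    coefficients = c(not_a_feature = 1)))
  expect_error(generate_exertion(ros, feats, bad_cfg, seed = 1), "schema|neither")
})

test_that("an intercept-only fit recovers the configured latent ICC of 0.63", {
  cfg <- generative_config(
    n_shifts = 200, dropout = 0,
    me_model = list(coefficients = numeric(), var_u0 = 0.63, var_e = 0.37,
                    var_u1 = 0))
  feats <- simulate_features(cfg, seed = 31)
  ros <- generate_roster(cfg, seed = 31)
  ratings <- generate_exertion(ros, feats, cfg, seed = 31)
  ratings$me_z <- (ratings$me - mean(ratings$me)) / sd(ratings$me)
  fit <- fit_lmm(lmm_spec("me_z"), ratings)
  expect_equal(icc(fit), 0.63, tolerance = 0.05)
})

test_that("a full simulated study is deterministic under a fixed seed", {
  cfg <- generative_config(n_shifts = 3, frame_rate = 0.1,
                           ambient_rate = 1 / 600)
  s1 <- simulate_study(cfg, seed = 77)
  s2 <- simulate_study(cfg, seed = 77)
  expect_identical(s1$analysis_table, s2$analysis_table)
  expect_identical(s1$roster, s2$roster)
  s3 <- simulate_study(cfg, seed = 78)
  expect_false(identical(s1$analysis_table, s3$analysis_table))
})

test_that("the analysis table has the documented schema", {
  cfg <- generative_config(n_shifts = 4, frame_rate = 0.1,
                           ambient_rate = 1 / 600)
  study <- simulate_study(cfg, seed = 5)
  tbl <- study$analysis_table
  expect_true(all(c("shift_id", "segment_index", "me", "pe", "weekday") %in%
                    names(tbl)))
  expect_true(all(task_demand_names(cfg) %in% names(tbl)))
  expect_true(all(feature_registry()$name %in% names(tbl)))
  # undefined features propagate to missing ratings; observed ones are Borg
  expect_true(all(tbl$me >= 6 & tbl$me <= 20, na.rm = TRUE))
  expect_true(all(tbl$pe >= 6 & tbl$pe <= 20, na.rm = TRUE))
  expect_false(any(grepl("^eff_", names(tbl))))   # latent effects not leaked
})
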