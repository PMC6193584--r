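zscore <- function(x) {
  s <- sd(x, na.rm = TRUE)
  m <- mean(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(x - m)
  (x - m) / s
}

draw_random_effects <- function(n, var_u0, var_u1, cov_u01) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  u0 <- sqrt(var_u0) * z1
  if (var_u1 > 0 && var_u0 > 0) {
    b <- cov_u01 / sqrt(var_u0)
    resid <- max(var_u1 - b^2, 0)
    u1 <- b * z1 + sqrt(resid) * z2
  } else {
    u1 <- sqrt(var_u1) * z2
  }
  list(u0 = u0, u1 = u1)
}

term_columns <- function(term, feat_z, l2_z) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  vals <- lapply(parts, function(p) {
    if (!is.null(feat_z[[p]])) return(feat_z[[p]])
    if (!is.null(l2_z[[p]])) return(l2_z[[p]])
    stop("exertion model term '", term, "' needs variable '", p,
         "', which is neither a feature nor a task demand", call. = FALSE)
  })
  Reduce(`*`, vals)
}

#' Generate Borg exertion ratings from segment features
#'
#' Fills in the mental (ME) and physical (PE) exertion ratings of a study.
#' For each response, the latent exertion of segment `i` in shift `j` is
#'
#' `y_ij = intercept + x_ij' beta + u0_j + u1_j * s_ij + e_ij`
#'
#' where `x_ij` are the z-scored features and task demands named by the
#' model's coefficient vector (`"a:b"` names are products), `u0_j` is the
#' shift random intercept, `u1_j` the shift random slope on the designated
#' slope feature `s_ij`, and `e_ij` residual noise. The latent value is
#' mapped to the Borg 6-20 scale by `round(center + scale * y)` and clamped.
#' A segment's ratings are missing with probability `config$dropout`
#' (at least one rated segment is kept per shift). The full ground truth
#' (coefficients, variance components, drawn random effects, latent values)
#' is attached as attribute `"truth"` for recovery testing.
#'
#' @param roster Roster from [generate_roster()].
#' @param features Feature matrix keyed by (`shift_id`, `segment_index`).
#' @param config A [generative_config()].
#' @param seed Integer seed.
#' @return A tibble (`shift_id`, `segment_index`, `rated`, `me`, `pe`) with
#'   attribute `truth`.
#' @export
generate_exertion <- function(roster, features,
                              config = generative_config(),
                              seed = config$seed) {
  stopifnot(all(c("shift_id", "segment_index") %in% names(features)))
  set.seed(seed)
  n <- nrow(features)
  shift_idx <- match(features$shift_id, roster$shift_id)
  if (anyNA(shift_idx)) stop("features contain shifts absent from the roster")

  feat_cols <- setdiff(names(features), c("shift_id", "segment_index"))
  feat_z <- as.list(dplyr::mutate(features[feat_cols],
                                  dplyr::across(dplyr::everything(), zscore)))
  l2_cols <- intersect(task_demand_names(config), names(roster))
  l2_shift <- dplyr::mutate(roster[l2_cols],
                            dplyr::across(dplyr::everything(), zscore))
  l2_z <- as.list(l2_shift[shift_idx, , drop = FALSE])

  truth <- list()
  ratings <- tibble::tibble(shift_id = features$shift_id,
                            segment_index = features$segment_index)
  for (resp in c("me", "pe")) {
    mod <- config[[paste0(resp, "_model")]]
    beta <- mod$coefficients
    fixed <- rep(mod$intercept, n)
    for (term in names(beta)) {
      fixed <- fixed + beta[[term]] * term_columns(term, feat_z, l2_z)
    }
    re <- draw_random_effects(nrow(roster), mod$var_u0, mod$var_u1,
                              mod$cov_u01)
    slope_x <- if (mod$var_u1 > 0) {
      term_columns(mod$slope_feature, feat_z, l2_z)
    } else {
      rep(0, n)
    }
    latent <- fixed + re$u0[shift_idx] + re$u1[shift_idx] * slope_x +
      rnorm(n, 0, sqrt(mod$var_e))
    borg <- pmin(20, pmax(6, round(config$borg$center +
                                     config$borg$scale * latent)))
    ratings[[resp]] <- as.integer(borg)
    truth[[resp]] <- list(coefficients = beta, intercept = mod$intercept,
                          var_u0 = mod$var_u0, var_e = mod$var_e,
                          var_u1 = mod$var_u1, cov_u01 = mod$cov_u01,
                          slope_feature = mod$slope_feature,
                          u0 = re$u0, u1 = re$u1, latent = latent,
                          borg_latent = config$borg$center +
                            config$borg$scale * latent)
  }

  rated <- runif(n) >= config$dropout
  for (s in unique(ratings$shift_id)) {
    rows <- which(ratings$shift_id == s)
    if (!any(rated[rows])) rated[rows[1]] <- TRUE
  }
  ratings$rated <- rated
  ratings$me[!rated] <- NA_integer_
  ratings$pe[!rated] <- NA_integer_
  truth$rated <- rated
  attr(ratings, "truth") <- truth
  ratings
}

#' Default per-feature intraclass correlations for the direct simulator
#'
#' Ambient conditions, time-allocation fractions and activity levels are
#' largely set by the shift's patient assignment, so they cluster strongly
#' within a shift; temporal-dynamics features (burstiness, entropy, speech
#' and walking timing) vary more from segment to segment.
#'
#' @return Named vector of ICC values over the [feature_registry()] names.
#' @export
default_feature_icc <- function() {
  reg <- feature_registry()
  icc <- setNames(rep(0.45, nrow(reg)), reg$name)
  stable <- reg$category %in% c("environmental_noise", "temperature") |
    grepl("^time_(patient|nursing|service|outside)", reg$name) |
    grepl("^activity", reg$name)
  icc[stable] <- 0.85
  icc
}

#' Directly simulate a clustered feature matrix
#'
#' A fast alternative to full stream simulation for Monte-Carlo work:
#' each feature is drawn as `sqrt(icc) * b_shift + sqrt(1 - icc) * w_segment`
#' with independent standard-normal components, giving unit-variance
#' features with the requested between-shift intraclass correlation.
#' Features are mutually independent; use the stream simulator when
#' realistic cross-feature structure matters.
#'
#' @param config A [generative_config()] (supplies `n_shifts`,
#'   `segments_per_shift`, and `feature_icc` overrides).
#' @param seed Integer seed.
#' @param features Character vector of feature names (default: the full
#'   registry).
#' @return A feature-matrix tibble keyed by (`shift_id`, `segment_index`).
#' @export
simulate_features <- function(config = generative_config(),
                              seed = config$seed,
                              features = feature_registry()$name) {
  set.seed(seed)
  icc <- default_feature_icc()
  if (!is.null(config$feature_icc)) {
    icc[names(config$feature_icc)] <- config$feature_icc
  }
  icc <- icc[features]
  icc[is.na(icc)] <- 0.45
  names(icc) <- features
  G <- config$n_shifts
  m <- config$segments_per_shift
  out <- tibble::tibble(
    shift_id = rep(sprintf("S%03d", seq_len(G)), each = m),
    segment_index = rep(seq_len(m), G)
  )
  for (f in features) {
    b <- rnorm(G)[rep(seq_len(G), each = m)]
    w <- rnorm(G * m)
    out[[f]] <- sqrt(icc[[f]]) * b + sqrt(1 - icc[[f]]) * w
  }
  out
}

#' Simulate a complete badge-sensor study
#'
#' Runs the whole generative chain: roster with task demands, per-segment
#' event streams, feature extraction, and Borg exertion ratings, and merges
#' everything into a single analysis table (one row per rated segment).
#' With `use_streams = FALSE` the feature matrix is drawn directly by
#' [simulate_features()] instead of simulating and summarising raw streams,
#' which is orders of magnitude faster for Monte-Carlo studies.
#'
#' @param config A [generative_config()].
#' @param map A [unit_map()].
#' @param seed Integer seed.
#' @param use_streams Simulate raw streams and extract features (default),
#'   or draw the feature matrix directly.
#' @param keep_streams Retain the raw streams in the result (memory-heavy).
#' @param params A [feature_params()].
#' @return A list of class `sensor_study`: `roster`, `features`, `ratings`,
#'   `analysis_table`, `truth`, `config`, `seed`, and optionally `streams`.
#' @export
simulate_study <- function(config = generative_config(),
                           map = default_unit_map(), seed = config$seed,
                           use_streams = TRUE, keep_streams = FALSE,
                           params = feature_params()) {
  roster <- generate_roster(config, seed)
  if (nrow(roster) == 0) stop("cannot simulate a study with zero shifts")
  segs <- tidyr::expand_grid(shift_id = roster$shift_id,
                             segment_index = seq_len(config$segments_per_shift))
  streams <- NULL
  if (use_streams) {
    stream_list <- purrr::pmap(segs, function(shift_id, segment_index) {
      i <- match(shift_id, roster$shift_id)
      simulate_segment_streams(roster[i, ], map, config,
                               seed = seed + 1000L * i + segment_index)
    })
    seg_list <- purrr::pmap(
      list(segs$shift_id, segs$segment_index, stream_list),
      function(s, k, st) list(shift_id = s, segment_index = k, streams = st))
    features <- build_feature_matrix(seg_list, map, params)
    if (keep_streams) streams <- stream_list
  } else {
    features <- simulate_features(config, seed)
  }
  ratings <- generate_exertion(roster, features, config,
                               seed = seed + 500009L)
  truth <- attr(ratings, "truth")

  observed <- c("shift_id", "date_class", task_demand_names(config))
  tbl <- dplyr::inner_join(features, ratings,
                           by = c("shift_id", "segment_index"))
  tbl <- dplyr::inner_join(tbl, roster[observed], by = "shift_id")
  tbl$weekday <- as.integer(tbl$date_class == "weekday")
  tbl <- tbl[tbl$rated, setdiff(names(tbl), "rated")]
  front <- c("shift_id", "segment_index", "date_class", "weekday",
             task_demand_names(config))
  tbl <- tbl[, c(front, setdiff(names(tbl), front))]

  structure(list(roster = roster, features = features, ratings = ratings,
                 analysis_table = tbl, truth = truth, config = config,
                 seed = seed, streams = streams),
            class = "sensor_study")
}

#' @export
print.sensor_study <- function(x, ...) {
  cat(sprintf("Synthetic badge-sensor study: %d shifts, %d rated segments (of %d)\n",
              nrow(x$roster), nrow(x$analysis_table), nrow(x$features)))
  cat(sprintf("  %d features, %d task demands; seed %d\n",
              nrow(feature_registry()), length(task_demand_names(x$config)),
              x$seed))
  invisible(x)
}
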