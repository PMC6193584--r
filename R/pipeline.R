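#' Pipeline run configuration
#'
#' @param mode Input mode: `"simulate"` (generate a synthetic study),
#'   `"ingest_table"` (read a prepared segment-level analysis table), or
#'   `"ingest_streams"` (read raw interval/frame CSVs written by
#'   [write_streams_csv()]).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param generative A [generative_config()] (simulate mode).
#' @param selection An [enet_config()].
#' @param sequence A [sequence_config()].
#' @param responses Responses to analyse (`"me"`, `"pe"`).
#' @param input Path to the analysis table CSV (ingest_table mode) or the
#'   stream directory (ingest_streams mode).
#' @param mapping Optional named character vector or YAML file path mapping
#'   internal column names to the input table's column names, so an
#'   externally prepared table with different headers can be ingested
#'   without code changes.
#' @param scale_features,scale_response Standardise features (z-score) and
#'   responses before modelling.
#' @param level2 Task-demand columns; defaults to the standard roster set.
#' @param out_dir Output directory for artifacts (`NULL` for none).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest_table", "ingest_streams"),
                       seed = 1L, generative = generative_config(seed = seed),
                       selection = enet_config(),
                       sequence = sequence_config(),
                       responses = c("me", "pe"), input = NULL,
                       mapping = NULL, scale_features = TRUE,
                       scale_response = TRUE, level2 = NULL,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode != "simulate" && is.null(input)) {
    stop("ingest modes require an input path")
  }
  structure(list(mode = mode, seed = as.integer(seed), generative = generative,
                 selection = selection, sequence = sequence,
                 responses = responses, input = input, mapping = mapping,
                 scale_features = scale_features,
                 scale_response = scale_response, level2 = level2,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [run_config()]; the `generative`, `selection` and
#' `sequence` keys hold the nested configurations.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  seed <- as.integer(raw$seed %||% 1L)
  args$seed <- seed
  args$generative <- if (is.null(raw$generative)) {
    generative_config(seed = seed)
  } else {
    do.call(generative_config, c(raw$generative, list(seed = seed)))
  }
  args$selection <- do.call(enet_config, raw$selection %||% list())
  args$sequence <- do.call(sequence_config, raw$sequence %||% list())
  if (!is.null(raw$mapping) && is.character(raw$mapping) &&
      length(raw$mapping) == 1 && file.exists(raw$mapping)) {
    args$mapping <- unlist(yaml::read_yaml(raw$mapping))
  } else if (!is.null(raw$mapping)) {
    args$mapping <- unlist(raw$mapping)
  }
  do.call(run_config, args)
}

#' Ingest a prepared segment-level analysis table
#'
#' Reads a CSV with one row per rated shift segment. A mapping (internal
#' name = file column name) renames external headers onto the internal
#' schema; unmapped internal names are taken as-is when present. The table
#' must contain `shift_id`, `segment_index`, at least one response column
#' (`me`, `pe`), and numeric feature/task-demand columns.
#'
#' @param path CSV path.
#' @param mapping Named character vector or YAML file path.
#' @return A tibble.
#' @export
ingest_analysis_table <- function(path, mapping = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping) &&
      is.null(names(mapping))) {
    mapping <- unlist(yaml::read_yaml(mapping))
  }
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(tbl))
    if (length(missing_src)) {
      stop("mapped source columns absent from table: ",
           paste(missing_src, collapse = ", "))
    }
    for (internal in names(mapping)) {
      tbl[[internal]] <- tbl[[mapping[[internal]]]]
    }
    tbl <- tbl[unique(c(names(mapping),
                        setdiff(names(tbl), unname(mapping))))]
  }
  required <- c("shift_id", "segment_index")
  miss <- setdiff(required, names(tbl))
  if (length(miss)) {
    stop("analysis table lacks required columns: ",
         paste(miss, collapse = ", "))
  }
  if (!any(c("me", "pe") %in% names(tbl))) {
    stop("analysis table must contain an 'me' or 'pe' response column")
  }
  tbl
}

feature_columns_in <- function(tbl) {
  intersect(feature_registry()$name, names(tbl))
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2000000000L
}

#' Run the full analysis pipeline
#'
#' Orchestrates input (simulate or ingest), grand-mean
#' centring/standardisation, elastic-net screening of main effects and
#' pairwise interactions, the staged M0-M4 mixed-model sequence per
#' response, and interaction-plot data for the retained product terms.
#' All randomness derives from `config$seed`, so a rerun with the same
#' configuration reproduces every artifact byte for byte.
#'
#' @param config A [run_config()].
#' @return An object of class `analysis_report`: per-response `selection`
#'   and `sequence` results, `analysis_table` (standardised), `tables`
#'   (tidy staged tables from [sequence_table()]), `interaction_plots`
#'   (data for [interaction_plot_data()] terms), and `provenance` (seed,
#'   configuration hash, row counts). Artifacts are written under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config = run_config()) {
  study <- NULL
  if (config$mode == "simulate") {
    study <- simulate_study(config$generative, seed = config$seed)
    tbl <- study$analysis_table
  } else if (config$mode == "ingest_table") {
    tbl <- ingest_analysis_table(config$input, config$mapping)
  } else {
    stop("ingest_streams mode: read streams with read_streams_csv(), ",
         "extract features with build_feature_matrix(), then use ",
         "ingest_table mode on the merged table")
  }

  feats <- feature_columns_in(tbl)
  if (!length(feats)) stop("no recognised feature columns in analysis table")
  level2 <- config$level2 %||%
    intersect(task_demand_names(config$generative), names(tbl))
  responses <- intersect(config$responses, names(tbl))
  if (!length(responses)) stop("no requested response column present")

  # listwise-complete on modelled columns; log drops
  used <- c("shift_id", "segment_index", responses, feats, level2)
  complete <- complete.cases(tbl[setdiff(used, responses)])
  dropped <- sum(!complete)
  tbl <- tbl[complete, , drop = FALSE]

  std <- standardize(tbl, scale = config$scale_features,
                     cols = c(feats, level2))
  if (config$scale_response) {
    for (r in responses) std[[r]] <- zscore(std[[r]])
  }

  selections <- list()
  sequences <- list()
  tables <- list()
  plots <- list()
  for (r in responses) {
    ok <- !is.na(std[[r]])
    X <- as.matrix(std[ok, feats])
    y <- std[[r]][ok]
    sel_cfg <- config$selection
    sel_cfg$fold_seed <- derive_seed(config$seed, 100 + match(r, responses))
    if (sum(ok) >= max(sel_cfg$nfolds, config$sequence$min_rows)) {
      sel <- screen_interactions(X, y, sel_cfg)
    } else {
      # too few rated segments to cross-validate: empty screen; the model
      # sequence below will stop after the null model with its own warning
      sel <- structure(list(
        main_effects = character(),
        interactions = matrix(character(), 0, 2,
                              dimnames = list(NULL,
                                              c("parent1", "parent2"))),
        survivors = character(), stage1 = NULL, stage2 = NULL),
        class = "selection_result")
    }
    selections[[r]] <- sel

    products <- if (nrow(sel$interactions)) {
      apply(sel$interactions, 1, paste, collapse = ":")
    } else {
      character()
    }
    seq_r <- run_model_sequence(std[ok, , drop = FALSE], r,
                                level1_candidates = sel$main_effects,
                                level1_products = products,
                                level2_candidates = level2,
                                config = config$sequence)
    sequences[[r]] <- seq_r
    tables[[r]] <- sequence_table(seq_r)

    final <- seq_r$stages[[length(seq_r$stages)]]$fit
    prod_terms <- c(final$spec$level1_products, final$spec$cross)
    plots[[r]] <- purrr::map(setNames(prod_terms, prod_terms), function(tt) {
      parts <- strsplit(tt, ":", fixed = TRUE)[[1]]
      interaction_plot_data(final, tt, moderator = parts[1])
    })
  }

  provenance <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_rows = nrow(std), n_dropped = dropped,
    n_shifts = length(unique(std$shift_id)),
    created = "run_pipeline"
  )

  report <- structure(list(
    analysis_table = std, selections = selections, sequences = sequences,
    tables = tables, interaction_plots = plots, provenance = provenance,
    study = study, config = config
  ), class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Workload analysis report: %d segments, %d shifts (seed %d)\n",
              x$provenance$n_rows, x$provenance$n_shifts, x$provenance$seed))
  for (r in names(x$sequences)) {
    cat("\n-- response:", r, "--\n")
    print(x$sequences[[r]])
  }
  invisible(x)
}

#' Write report artifacts to disk
#'
#' Writes the standardised analysis table, per-response selection summaries
#' (JSON), staged result tables (CSV), interaction-plot datasets (CSV), and
#' a JSON report header with provenance (seed, configuration hash, row
#' counts) so every artifact is regenerable from configuration plus seed.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "analysis_table.csv")
  readr::write_csv(report$analysis_table, p)
  paths <- c(paths, p)
  for (r in names(report$sequences)) {
    p <- file.path(dir, paste0("sequence_", r, ".csv"))
    readr::write_csv(report$tables[[r]], p)
    paths <- c(paths, p)
    sel <- report$selections[[r]]
    p <- file.path(dir, paste0("selection_", r, ".json"))
    jsonlite::write_json(list(
      main_effects = sel$main_effects,
      interactions = apply(sel$interactions, 1, paste, collapse = ":"),
      lambda_min = sel$stage1$lambda_min,
      lambda_lenient = sel$stage1$lambda_lenient
    ), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
    for (tt in names(report$interaction_plots[[r]])) {
      p <- file.path(dir, paste0("interaction_", r, "_",
                                 gsub(":", "_x_", tt, fixed = TRUE), ".csv"))
      readr::write_csv(report$interaction_plots[[r]][[tt]], p)
      paths <- c(paths, p)
    }
  }
  summary <- list(provenance = report$provenance,
                  responses = names(report$sequences))
  for (r in names(report$sequences)) {
    s <- report$sequences[[r]]
    summary[[paste0("icc_", r)]] <- s$icc
    summary[[paste0("reliability_", r)]] <- s$reliability
  }
  p <- file.path(dir, "report.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' Interaction-plot dataset from a fitted model
#'
#' For a retained product term, predicts the response over the observed
#' range of the focal variable while the moderator is held at its observed
#' minimum and maximum (on the analysis scale), all other fixed covariates
#' at their observed means, with 95% confidence bands from the fixed-effect
#' covariance matrix.
#'
#' @param fit An `lmm_fit` containing `term`.
#' @param term The `"a:b"` product term to display.
#' @param moderator Which parent is the moderator (default the second).
#' @param n_points Grid size over the focal range.
#' @return A tibble with `focal`, `moderator`, `focal_value`,
#'   `moderator_level` (`"min"`/`"max"`), `moderator_value`, `fit`, `lwr`,
#'   `upr`.
#' @export
interaction_plot_data <- function(fit, term, moderator = NULL,
                                  n_points = 50) {
  terms <- fit$coefficients$term
  if (!term %in% terms) {
    stop("term '", term, "' is not in the fitted model")
  }
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  moderator <- moderator %||% parts[2]
  if (!moderator %in% parts) {
    stop("moderator must be one of the product's parents")
  }
  focal <- setdiff(parts, moderator)

  frame <- fit$model@frame
  covars <- setdiff(terms, "(Intercept)")
  simple <- covars[!grepl(":", covars, fixed = TRUE)]
  mins <- vapply(frame[simple], min, numeric(1))
  maxs <- vapply(frame[simple], max, numeric(1))
  means <- vapply(frame[simple], mean, numeric(1))

  grid <- tidyr::expand_grid(
    focal_value = seq(mins[[focal]], maxs[[focal]], length.out = n_points),
    moderator_level = c("min", "max")
  )
  grid$moderator_value <- ifelse(grid$moderator_level == "min",
                                 mins[[moderator]], maxs[[moderator]])

  X <- matrix(0, nrow(grid), length(terms),
              dimnames = list(NULL, terms))
  if ("(Intercept)" %in% terms) X[, "(Intercept)"] <- 1
  for (v in simple) X[, v] <- means[[v]]
  X[, focal] <- grid$focal_value
  X[, moderator] <- grid$moderator_value
  for (tt in covars[grepl(":", covars, fixed = TRUE)]) {
    pp <- strsplit(tt, ":", fixed = TRUE)[[1]]
    X[, tt] <- X[, pp[1]] * X[, pp[2]]
  }

  beta <- fit$coefficients$estimate
  V <- as.matrix(vcov(fit$model))
  pred <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  tibble::tibble(focal = focal, moderator = moderator,
                 focal_value = grid$focal_value,
                 moderator_level = grid$moderator_level,
                 moderator_value = grid$moderator_value,
                 fit = pred, lwr = pred - qnorm(0.975) * se,
                 upr = pred + qnorm(0.975) * se)
}

#' Plot an interaction dataset
#'
#' Convenience ggplot of [interaction_plot_data()] output: one line per
#' moderator bound with its confidence ribbon.
#'
#' @param data Output of [interaction_plot_data()].
#' @return A ggplot object.
#' @export
plot_interaction <- function(data) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data$focal_value, y = .data$fit,
                                     colour = .data$moderator_level,
                                     fill = .data$moderator_level)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(max = "blue", min = "red")) +
    ggplot2::scale_fill_manual(values = c(max = "blue", min = "red")) +
    ggplot2::labs(x = unique(data$focal),
                  y = "predicted exertion (standardised)",
                  colour = unique(data$moderator),
                  fill = unique(data$moderator))
}

#' Write raw event streams as CSV
#'
#' Location intervals go to `<prefix>_intervals.csv` (segment_id, zone_id,
#' start_s, end_s) and all frame series to `<prefix>_frames.csv` in long
#' format (segment_id, t_s, channel, value; ambient channels additionally
#' keyed by zone in the channel name).
#'
#' @param streams An `event_streams` object.
#' @param dir Output directory.
#' @param segment_id Identifier written into the files.
#' @return Invisibly, the two paths.
#' @export
write_streams_csv <- function(streams, dir, segment_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pi <- file.path(dir, paste0(segment_id, "_intervals.csv"))
  iv <- streams$intervals
  iv$segment_id <- segment_id
  readr::write_csv(iv[c("segment_id", "zone_id", "start_s", "end_s")], pi)

  long <- dplyr::bind_rows(
    tibble::tibble(t_s = streams$speech$t_s, channel = "speaking",
                   value = as.numeric(streams$speech$speaking)),
    tibble::tibble(t_s = streams$speech$t_s, channel = "volume_db",
                   value = streams$speech$volume_db),
    tibble::tibble(t_s = streams$speech$t_s, channel = "pitch_hz",
                   value = streams$speech$pitch_hz),
    tibble::tibble(t_s = streams$accel$t_s, channel = "magnitude_g",
                   value = streams$accel$magnitude_g),
    tibble::tibble(t_s = streams$ambient$t_s,
                   channel = paste0("noise_db@", streams$ambient$zone_id),
                   value = streams$ambient$noise_db),
    tibble::tibble(t_s = streams$ambient$t_s,
                   channel = paste0("temperature_c@", streams$ambient$zone_id),
                   value = streams$ambient$temperature_c)
  )
  long$segment_id <- segment_id
  pf <- file.path(dir, paste0(segment_id, "_frames.csv"))
  readr::write_csv(long[c("segment_id", "t_s", "channel", "value")], pf)
  invisible(c(pi, pf))
}

#' Read raw event streams written by [write_streams_csv()]
#'
#' @param dir Directory holding the CSVs.
#' @param segment_id Segment identifier.
#' @param map A [unit_map()] used to restore zone classes.
#' @param segment_length Segment length in seconds.
#' @return An `event_streams` object.
#' @export
read_streams_csv <- function(dir, segment_id, map = default_unit_map(),
                             segment_length = 14400) {
  iv <- readr::read_csv(file.path(dir, paste0(segment_id, "_intervals.csv")),
                        show_col_types = FALSE, progress = FALSE)
  iv$zone_class <- zone_class_of(map)[iv$zone_id]
  fr <- readr::read_csv(file.path(dir, paste0(segment_id, "_frames.csv")),
                        show_col_types = FALSE, progress = FALSE)
  pick <- function(ch) fr[fr$channel == ch, ]
  sp <- pick("speaking")
  speech <- tibble::tibble(t_s = sp$t_s, speaking = sp$value > 0.5,
                           volume_db = pick("volume_db")$value,
                           pitch_hz = pick("pitch_hz")$value)
  ac <- pick("magnitude_g")
  accel <- tibble::tibble(t_s = ac$t_s, magnitude_g = ac$value)
  amb <- fr[grepl("@", fr$channel, fixed = TRUE), ]
  amb$zone_id <- sub("^[^@]*@", "", amb$channel)
  amb$kind <- sub("@.*$", "", amb$channel)
  noise <- amb[amb$kind == "noise_db", ]
  temp <- amb[amb$kind == "temperature_c", ]
  ambient <- tibble::tibble(t_s = noise$t_s, zone_id = noise$zone_id,
                            zone_class = zone_class_of(map)[noise$zone_id],
                            noise_db = noise$value,
                            temperature_c = temp$value)
  structure(list(intervals = iv[c("zone_id", "zone_class", "start_s",
                                  "end_s")],
                 speech = speech, accel = accel, ambient = ambient,
                 segment_length = segment_length, frame_rate = NA_real_),
            class = "event_streams")
}
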