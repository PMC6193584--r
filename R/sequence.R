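drop_term <- function(spec, term) {
  for (slot in c("level1", "level1_products", "level2", "cross")) {
    spec[[slot]] <- setdiff(spec[[slot]], term)
  }
  spec
}

product_parents <- function(terms) {
  unique(unlist(strsplit(terms, ":", fixed = TRUE)))
}

droppable_terms <- function(spec, protected) {
  terms <- spec_fixed_terms(spec)
  parents <- product_parents(c(spec$level1_products, spec$cross))
  ok <- !(terms %in% protected)
  is_main <- terms %in% c(spec$level1, spec$level2)
  # a main effect is frozen while any product contains it, and while it
  # carries a random slope
  ok <- ok & !(is_main & (terms %in% parents | terms %in% spec$slopes))
  terms[ok]
}

#' Hierarchical backward elimination
#'
#' Iteratively refits the model and removes the single least-significant
#' droppable term with `p >= alpha` until none remains. A main effect is not
#' droppable while any retained product contains it (strong hierarchy) or
#' while it carries a random slope; `protected` terms are never dropped.
#' Ties in p-value are broken lexicographically by term name.
#'
#' @param spec An [lmm_spec()].
#' @param data Analysis table.
#' @param alpha Retention threshold (default 0.05).
#' @param protected Terms never considered for removal.
#' @return List with the reduced `spec`, the final `fit`, and an
#'   elimination `log` tibble (step, term dropped, its p-value).
#' @export
backward_eliminate <- function(spec, data, alpha = 0.05,
                               protected = character()) {
  log <- tibble::tibble(step = integer(), term = character(), p = numeric())
  step <- 0L
  fit <- fit_lmm(spec, data)
  repeat {
    cand <- droppable_terms(spec, protected)
    if (!length(cand)) break
    tab <- fit$coefficients
    tab <- tab[tab$term %in% cand & tab$p >= alpha, , drop = FALSE]
    if (!nrow(tab)) break
    tab <- tab[order(-tab$p, tab$term), ]
    victim <- tab$term[1]
    step <- step + 1L
    log <- dplyr::bind_rows(log, tibble::tibble(step = step, term = victim,
                                                p = tab$p[1]))
    spec <- drop_term(spec, victim)
    fit <- fit_lmm(spec, data)
  }
  list(spec = spec, fit = fit, log = log)
}

prune_candidates <- function(dat, response, mains, products, cap) {
  score <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    v <- Reduce(`*`, lapply(parts, function(p) dat[[p]]))
    abs(stats::cor(v, dat[[response]], use = "complete.obs"))
  }
  if (length(mains) + length(products) <= cap) {
    return(list(mains = mains, products = products))
  }
  prod_rank <- products[order(-vapply(products, score, numeric(1)))]
  main_rank <- mains[order(-vapply(mains, score, numeric(1)))]
  # products cede space to mains; retained products pull their parents back in
  n_main <- min(length(main_rank), max(cap - 2L, 1L))
  keep_main <- main_rank[seq_len(n_main)]
  keep_prod <- character()
  for (pr in prod_rank) {
    parts <- strsplit(pr, ":", fixed = TRUE)[[1]]
    extra <- length(setdiff(parts, keep_main)) + 1L
    if (length(keep_main) + length(keep_prod) + extra <= cap) {
      keep_main <- union(keep_main, parts)
      keep_prod <- c(keep_prod, pr)
    }
  }
  list(mains = keep_main[seq_len(min(length(keep_main), cap))],
       products = keep_prod)
}

drop_collinear <- function(spec, dat) {
  repeat {
    fit_try <- tryCatch(fit_lmm(spec, dat), error = function(e) e)
    if (!inherits(fit_try, "error")) return(spec)
    if (!grepl("collinear", conditionMessage(fit_try))) stop(fit_try)
    bad <- sub(".*collinear term\\(s\\): ", "", conditionMessage(fit_try))
    bad <- strsplit(bad, ", ", fixed = TRUE)[[1]]
    # remove products before main effects so hierarchy cannot break
    bad_prod <- intersect(bad, c(spec$level1_products, spec$cross))
    victims <- if (length(bad_prod)) bad_prod else bad
    for (v in victims) spec <- drop_term(spec, v)
    if (!length(spec_fixed_terms(spec))) return(spec)
  }
}

#' Configuration of the staged model sequence
#'
#' @param alpha Significance level for backward elimination and cross-level
#'   screening.
#' @param slope_alpha Significance level of the likelihood-ratio test for
#'   adding a random slope.
#' @param max_slopes Maximum number of random slopes accepted.
#' @param slope_candidates Level-1 features eligible for a random slope;
#'   defaults to all Level-1 candidates (not only the fixed-effect
#'   survivors, so a feature whose fixed effect was eliminated can still
#'   show slope variation).
#' @param boundary_correction Halve the slope LR p-value to account for the
#'   variance parameter's boundary null; off by default so the naive
#'   chi-squared df = 2 test is used.
#' @param stage_gate Keep the terms added at the Level-1 and Level-2 stages
#'   only when the stage's deviance reduction passes the likelihood-ratio
#'   test at `alpha` (model comparison by deviance is the acceptance
#'   criterion for each stage); otherwise the stage reverts to the previous
#'   model.
#' @param min_rows,min_groups Below these, the sequence stops after the null
#'   model with a small-sample warning.
#' @return A list of class `sequence_config`.
#' @export
sequence_config <- function(alpha = 0.05, slope_alpha = 0.05,
                            max_slopes = 2L, slope_candidates = NULL,
                            boundary_correction = FALSE, stage_gate = TRUE,
                            min_rows = 12L, min_groups = 3L) {
  structure(list(alpha = alpha, slope_alpha = slope_alpha,
                 max_slopes = as.integer(max_slopes),
                 slope_candidates = slope_candidates,
                 boundary_correction = boundary_correction,
                 stage_gate = stage_gate,
                 min_rows = as.integer(min_rows),
                 min_groups = as.integer(min_groups)),
            class = "sequence_config")
}

#' Run the staged two-level model sequence
#'
#' The five-stage analysis of one exertion response:
#' \describe{
#'   \item{M0}{intercept-only model with shift random intercepts, tested by
#'     likelihood ratio against the pooled (no-grouping) null; ICC and
#'     group-mean reliability are computed here.}
#'   \item{M1}{all Level-1 candidates (sensor features and their selected
#'     products) added, then hierarchically backward-eliminated.}
#'   \item{M2}{Level-2 task-demand candidates added and eliminated among
#'     themselves (M1 survivors retained).}
#'   \item{M3}{random slopes tried one candidate at a time; a slope is kept
#'     when its likelihood-ratio test (naive chi-squared, df = 2 per slope
#'     plus 1 if the feature's fixed effect is newly added) passes
#'     `slope_alpha`; afterwards fixed terms that have become
#'     non-significant are re-eliminated (Level-2 terms and slope carriers
#'     retained).}
#'   \item{M4}{cross-level products between task demands and the retained
#'     random-slope features are screened one at a time at `alpha`; those
#'     passing enter jointly with their Level-2 parents and are
#'     backward-eliminated. Without a retained slope there is no slope
#'     variation to moderate, and M4 equals M3.}
#' }
#' Per stage the fit, the stage likelihood-ratio test, elimination logs, and
#' pseudo-R-squared relative to M0 (slope variation relative to M3) are
#' reported.
#'
#' @param data Analysis table (features standardised, response standardised
#'   or raw Borg).
#' @param response Response column name.
#' @param level1_candidates Level-1 main-effect candidates.
#' @param level1_products `"a:b"` Level-1 product candidates (parents are
#'   added to the candidate mains automatically).
#' @param level2_candidates Level-2 (task demand) candidates.
#' @param config A [sequence_config()].
#' @param group Grouping column.
#' @return An object of class `model_sequence`.
#' @export
run_model_sequence <- function(data, response, level1_candidates,
                               level1_products = character(),
                               level2_candidates = character(),
                               config = sequence_config(),
                               group = "shift_id") {
  level1_candidates <- union(level1_candidates,
                             setdiff(product_parents(level1_products),
                                     level2_candidates))
  vars <- unique(c(response, group, level1_candidates,
                   product_parents(level1_products), level2_candidates))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("analysis table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dat <- data[complete.cases(data[vars]), , drop = FALSE]
  n_dropped <- nrow(data) - nrow(dat)
  G <- length(unique(dat[[group]]))

  stages <- list()
  pooled <- fit_pooled_null(dat, response)
  spec0 <- lmm_spec(response, group = group)
  fit0 <- fit_lmm(spec0, dat)
  stages$M0 <- list(fit = fit0, lr = lr_test(fit0, pooled),
                    log = NULL, label = "Intercept only")
  out <- structure(list(
    response = response, stages = stages,
    icc = icc(fit0), reliability = group_mean_reliability(fit0),
    n_obs = fit0$n_obs, n_groups = fit0$n_groups, n_dropped = n_dropped,
    pooled_null = pooled, config = config, complete = FALSE
  ), class = "model_sequence")

  if (nrow(dat) < config$min_rows || G < config$min_groups) {
    warning(sprintf(
      "only %d rows in %d groups: stopping after the null model", nrow(dat), G))
    return(out)
  }

  # keep the starting model estimable: rank candidates by marginal
  # correlation with the response and cap the count so Level-1 containment
  # df stay positive, then drop any terms the design cannot separate
  pruned <- prune_candidates(dat, response, level1_candidates,
                             level1_products,
                             cap = max(nrow(dat) - G - 5L, 1L))
  level1_candidates <- pruned$mains
  level1_products <- pruned$products

  # M1: Level-1 fixed effects
  if (length(level1_candidates)) {
    spec1_full <- lmm_spec(response, level1 = level1_candidates,
                           level1_products = level1_products, group = group)
    spec1_full <- drop_collinear(spec1_full, dat)
    be1 <- backward_eliminate(spec1_full, dat, config$alpha)
    lr1 <- if (length(spec_fixed_terms(be1$spec))) {
      lr_test(be1$fit, fit0)
    }
    if (!is.null(lr1) &&
        (!config$stage_gate || (!is.na(lr1$p) && lr1$p <= config$alpha))) {
      stages$M1 <- list(fit = be1$fit, lr = lr1,
                        log = be1$log, label = "+ Level 1 predictors")
    } else {
      stages$M1 <- list(fit = fit0, lr = NULL, log = be1$log,
                        label = "+ Level 1 predictors (none retained)")
    }
  } else {
    stages$M1 <- list(fit = fit0, lr = NULL, log = NULL,
                      label = "+ Level 1 predictors (no candidates)")
  }
  cur <- stages$M1$fit

  # M2: Level-2 task demands (capped so Level-2 containment df stay positive)
  if (length(level2_candidates)) {
    l2 <- prune_candidates(dat, response, level2_candidates, character(),
                           cap = max(G - 3L, 1L))$mains
    spec2_full <- cur$spec
    spec2_full$level2 <- union(spec2_full$level2, l2)
    spec2_full <- drop_collinear(spec2_full, dat)
    be2 <- backward_eliminate(spec2_full, dat, config$alpha,
                              protected = spec_fixed_terms(cur$spec))
    lr2 <- if (length(setdiff(spec_fixed_terms(be2$spec),
                              spec_fixed_terms(cur$spec)))) {
      lr_test(be2$fit, cur)
    }
    if (!is.null(lr2) &&
        (!config$stage_gate || (!is.na(lr2$p) && lr2$p <= config$alpha))) {
      stages$M2 <- list(fit = be2$fit, lr = lr2,
                        log = be2$log, label = "+ Level 2 predictors")
    } else {
      stages$M2 <- list(fit = cur, lr = NULL, log = be2$log,
                        label = "+ Level 2 predictors (none retained)")
    }
  } else {
    stages$M2 <- list(fit = cur, lr = NULL, log = NULL,
                      label = "+ Level 2 predictors (no candidates)")
  }
  cur <- stages$M2$fit

  # M3: random coefficients, greedily one at a time
  slope_cands <- config$slope_candidates %||% level1_candidates
  slope_lr <- NULL
  accepted <- character()
  while (length(accepted) < config$max_slopes) {
    remaining <- setdiff(slope_cands, cur$spec$slopes)
    if (!length(remaining)) break
    trials <- purrr::map(remaining, function(s) {
      sp <- cur$spec
      sp$level1 <- union(sp$level1, s)
      sp$slopes <- union(sp$slopes, s)
      f <- tryCatch(fit_lmm(sp, dat), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      lt <- tryCatch(lr_test(f, cur), error = function(e) NULL)
      if (is.null(lt)) return(NULL)
      if (config$boundary_correction) lt$p <- lt$p / 2
      list(feature = s, fit = f, lr = lt)
    })
    trials <- purrr::compact(trials)
    if (!length(trials)) break
    ps <- vapply(trials, function(tr) tr$lr$p, numeric(1))
    best <- trials[[which.min(ps)]]
    if (is.na(best$lr$p) || best$lr$p > config$slope_alpha) break
    accepted <- c(accepted, best$feature)
    slope_lr <- best$lr
    cur <- best$fit
  }
  if (length(accepted)) {
    # drop fixed terms that lost significance once slopes entered
    be3 <- backward_eliminate(cur$spec, dat, config$alpha,
                              protected = c(cur$spec$level2, cur$spec$cross))
    stages$M3 <- list(fit = be3$fit, lr = slope_lr, log = be3$log,
                      label = "+ Random coefficients",
                      slopes = accepted)
  } else {
    stages$M3 <- list(fit = cur, lr = NULL, log = NULL,
                      label = "+ Random coefficients (none retained)",
                      slopes = character())
  }
  cur <- stages$M3$fit

  # M4: cross-level interactions moderate the random slopes, so candidates
  # pair each task demand with each retained random-slope feature
  carriers <- cur$spec$slopes
  cross_cand <- if (length(carriers)) {
    as.vector(outer(level2_candidates, carriers, paste, sep = ":"))
  } else {
    character()
  }
  screened <- character()
  for (cc in cross_cand) {
    parts <- strsplit(cc, ":", fixed = TRUE)[[1]]
    sp <- cur$spec
    sp$level2 <- union(sp$level2, parts[1])
    sp$cross <- union(sp$cross, cc)
    f <- tryCatch(fit_lmm(sp, dat), error = function(e) NULL)
    if (is.null(f)) next
    pv <- f$coefficients$p[f$coefficients$term == cc]
    if (length(pv) == 1 && !is.na(pv) && pv < config$alpha) {
      screened <- c(screened, cc)
    }
  }
  if (length(screened)) {
    sp <- cur$spec
    sp$level2 <- union(sp$level2, product_parents(screened)[
      product_parents(screened) %in% c(level2_candidates)])
    sp$cross <- union(sp$cross, screened)
    sp <- drop_collinear(sp, dat)
    be4 <- backward_eliminate(sp, dat, config$alpha,
                              protected = spec_fixed_terms(cur$spec))
    new_terms <- setdiff(spec_fixed_terms(be4$spec),
                         spec_fixed_terms(cur$spec))
    if (length(new_terms)) {
      stages$M4 <- list(fit = be4$fit, lr = lr_test(be4$fit, cur),
                        log = be4$log, label = "+ Cross-level interactions")
    } else {
      stages$M4 <- list(fit = cur, lr = NULL, log = be4$log,
                        label = "+ Cross-level interactions (none retained)")
    }
  } else {
    stages$M4 <- list(fit = cur, lr = NULL, log = NULL,
                      label = "+ Cross-level interactions (none retained)")
  }

  # variance modelled per stage, relative to the null model
  for (nm in names(stages)) {
    if (nm == "M0") next
    stages[[nm]]$r2 <- pseudo_r2(stages[[nm]]$fit, fit0)
  }
  if (length(stages$M3$slopes)) {
    stages$M4$r2$r2_slope <- pseudo_r2(stages$M4$fit, stages$M3$fit)$r2_slope
  }

  out$stages <- stages
  out$complete <- TRUE
  out
}

#' @export
print.model_sequence <- function(x, ...) {
  cat(sprintf("Staged two-level model sequence for '%s' (%d obs, %d shifts)\n",
              x$response, x$n_obs, x$n_groups))
  cat(sprintf("  ICC = %.2f, group-mean reliability = %.2f\n",
              x$icc, x$reliability))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    terms <- setdiff(st$fit$coefficients$term, "(Intercept)")
    cat(sprintf("  %s %s: %d terms, deviance %.2f", nm, st$label,
                length(terms), st$fit$deviance))
    if (!is.null(st$lr)) {
      cat(sprintf(", LR chi2(%d) = %.2f, p = %.3g", st$lr$df, st$lr$chisq,
                  st$lr$p))
    }
    cat("\n")
  }
  invisible(x)
}

#' Tidy per-stage results table
#'
#' A long-format staged-results table: one row
#' per (stage, term) for the fixed components, plus random components,
#' variance modelled, and model fit blocks.
#'
#' @param seq A `model_sequence`.
#' @return A tibble with columns `stage`, `block`, `term`, `estimate`, `se`,
#'   `df`, `p`.
#' @export
sequence_table <- function(seq) {
  reg <- feature_registry()
  label_of <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    lab <- vapply(parts, function(p) {
      i <- match(p, reg$name)
      if (!is.na(i)) reg$label[i] else gsub("_", " ", p)
    }, character(1))
    paste(lab, collapse = " x ")
  }
  rows <- purrr::imap(seq$stages, function(st, nm) {
    fixed <- dplyr::mutate(st$fit$coefficients, stage = nm,
                           block = "Fixed components",
                           term = vapply(term, function(tt)
                             if (tt == "(Intercept)") "Intercept" else
                               label_of(tt), character(1)))
    vc <- st$fit$varcomp
    rand <- tibble::tibble(
      stage = nm, block = "Random components",
      term = c("Between-shift variance", "Within-shift / residual variance",
               if (nrow(vc$slopes)) paste0("Slope variation (",
                                           vapply(vc$slopes$feature, label_of,
                                                  character(1)), ")")),
      estimate = c(vc$var_u0, vc$var_e, vc$slopes$var_u1),
      se = NA_real_, df = NA_real_, p = NA_real_)
    fitrow <- tibble::tibble(stage = nm, block = "Model fit",
                             term = "Deviance (-2 logLik)",
                             estimate = st$fit$deviance,
                             se = NA_real_, df = NA_real_, p = NA_real_)
    if (!is.null(st$lr)) {
      fitrow <- dplyr::bind_rows(fitrow, tibble::tibble(
        stage = nm, block = "Model fit", term = "LR chi-square",
        estimate = st$lr$chisq, se = NA_real_, df = st$lr$df, p = st$lr$p))
    }
    r2row <- NULL
    if (!is.null(st$r2)) {
      r2row <- tibble::tibble(
        stage = nm, block = "Variance modelled",
        term = c("R2 within shift", "R2 between shift",
                 if (!is.null(st$r2$r2_slope)) "R2 slope"),
        estimate = c(st$r2$r2_within, st$r2$r2_between,
                     if (!is.null(st$r2$r2_slope))
                       unname(st$r2$r2_slope[1])),
        se = NA_real_, df = NA_real_, p = NA_real_)
    }
    dplyr::bind_rows(fixed[c("stage", "block", "term", "estimate", "se",
                             "df", "p")], rand, r2row, fitrow)
  })
  dplyr::bind_rows(rows)
}
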