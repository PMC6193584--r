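#' Declare a two-level mixed-model specification
#'
#' Describes a two-level linear mixed model with shifts (groups) at Level 2
#' and four-hour segments at Level 1: segment-level fixed terms (sensor
#' features and feature-by-feature products), shift-level fixed terms (task
#' demands), cross-level products (task demand x feature), a random
#' intercept (always), and optional random slopes on Level-1 features with
#' an unstructured intercept-slope covariance.
#'
#' Strong hierarchy is enforced at construction: both parents of every
#' product must be present as main effects (the Level-1 parent of a
#' cross-level product in `level1`, the Level-2 parent in `level2`).
#'
#' @param response Response column name.
#' @param level1 Character vector of Level-1 (segment-level) fixed terms.
#' @param level1_products Character vector of `"a:b"` products of Level-1
#'   terms.
#' @param level2 Character vector of Level-2 (shift-level) fixed terms.
#' @param cross Character vector of `"l2:l1"` cross-level products.
#' @param slopes Level-1 features receiving a random slope.
#' @param group Grouping column (default `"shift_id"`).
#' @param method `"ML"` (default; required for likelihood-ratio tests across
#'   fixed effects) or `"REML"`.
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(response, level1 = character(),
                     level1_products = character(), level2 = character(),
                     cross = character(), slopes = character(),
                     group = "shift_id", method = c("ML", "REML")) {
  method <- match.arg(method)
  check_parents <- function(products, where1, where2 = where1) {
    for (pr in products) {
      parts <- strsplit(pr, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("product term must be 'a:b': ", pr)
      if (!parts[1] %in% where1 || !parts[2] %in% where2) {
        stop("strong hierarchy violated: parents of '", pr,
             "' must be included as main effects")
      }
    }
  }
  check_parents(level1_products, level1)
  check_parents(cross, level2, level1)
  if (!all(slopes %in% level1) && length(setdiff(slopes, level1))) {
    stop("random-slope features must be Level-1 main effects: ",
         paste(setdiff(slopes, level1), collapse = ", "))
  }
  structure(list(response = response, level1 = unique(level1),
                 level1_products = unique(level1_products),
                 level2 = unique(level2), cross = unique(cross),
                 slopes = unique(slopes), group = group, method = method),
            class = "lmm_spec")
}

spec_fixed_terms <- function(spec) {
  c(spec$level1, spec$level1_products, spec$level2, spec$cross)
}

spec_variables <- function(spec) {
  unique(c(spec$response, spec$group,
           unlist(strsplit(spec_fixed_terms(spec), ":", fixed = TRUE))))
}

spec_formula <- function(spec) {
  fixed <- spec_fixed_terms(spec)
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  rand <- if (length(spec$slopes)) {
    paste0("(1 + ", paste(spec$slopes, collapse = " + "), " | ", spec$group, ")")
  } else {
    paste0("(1 | ", spec$group, ")")
  }
  stats::as.formula(paste(spec$response, "~", rhs, "+", rand))
}

term_level <- function(spec, terms) {
  ifelse(terms %in% c(spec$level2), "level2",
         ifelse(terms %in% spec$cross, "cross",
                ifelse(terms %in% spec$level1_products, "level1_product",
                       "level1")))
}

#' @export
print.lmm_spec <- function(x, ...) {
  cat("Two-level LMM spec (", x$method, "): ",
      deparse(spec_formula(x)), "\n", sep = "")
  invisible(x)
}

#' Fit a two-level linear mixed model
#'
#' Fits the model declared by an [lmm_spec()] by maximum likelihood (the
#' default, so that models differing in fixed effects are comparable by
#' likelihood-ratio test) with `lme4`, then derives the quantities the
#' staged analysis needs: fixed effects with standard errors, containment
#' degrees of freedom and t-based p-values, variance components, and the
#' deviance.
#'
#' Containment degrees of freedom: Level-1 and cross-level terms (and the
#' intercept) get `df = N - G - p1`, where `N` is the number of rows, `G`
#' the number of groups and `p1` the number of Level-1 plus cross-level
#' fixed terms; Level-2 terms get `df = G - p2 - 1` with `p2` the number of
#' Level-2 terms.
#'
#' Rows with missing values in any model variable are dropped listwise (the
#' count is recorded). A rank-deficient fixed-effect design is an error
#' naming the collinear columns.
#'
#' @param spec An [lmm_spec()].
#' @param data Analysis table containing all model variables.
#' @return An object of class `lmm_fit`: `coefficients` (tibble with term,
#'   estimate, se, df, t, p, level), `varcomp` (list with `var_u0`,
#'   `var_e`, `slopes` tibble, `cov_u01`), `logLik`, `deviance`, `n_obs`,
#'   `n_groups`, `n_params`, `n_dropped`, `spec`, `model` (the underlying
#'   `merMod`), and `row_key` identifying the rows used.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "lmm_spec"))
  vars <- spec_variables(spec)
  vars <- unique(c(vars, spec$slopes))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("data is missing model variables: ",
         paste(missing_cols, collapse = ", "))
  }
  dat <- data[vars]
  ok <- complete.cases(dat)
  n_dropped <- sum(!ok)
  dat <- dat[ok, , drop = FALSE]
  dat[[spec$group]] <- factor(dat[[spec$group]])

  fixed_terms <- spec_fixed_terms(spec)
  fixed_formula <- stats::as.formula(paste(
    "~", if (length(fixed_terms)) paste(fixed_terms, collapse = "+") else "1"))
  X <- model.matrix(fixed_formula, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }

  fit <- lme4::lmer(spec_formula(spec), data = dat,
                    REML = identical(spec$method, "REML"),
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE,
                      optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10)))

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  # the model matrix orders interaction names by main-effect appearance;
  # map them back to the spec's own term strings
  canon <- vapply(names(est), function(nm) {
    if (!grepl(":", nm, fixed = TRUE)) return(nm)
    parts <- sort(strsplit(nm, ":", fixed = TRUE)[[1]])
    hit <- fixed_terms[vapply(strsplit(fixed_terms, ":", fixed = TRUE),
                              function(pp) identical(sort(pp), parts),
                              logical(1))]
    if (length(hit) == 1) hit else nm
  }, character(1))
  names(est) <- canon
  terms <- names(est)
  lvl <- c(intercept = "level1",
           setNames(term_level(spec, fixed_terms), fixed_terms))
  term_lvl <- ifelse(terms == "(Intercept)", "level1", lvl[terms])

  N <- nrow(dat)
  G <- nlevels(dat[[spec$group]])
  p1 <- length(spec$level1) + length(spec$level1_products) +
    length(spec$cross)
  p2 <- length(spec$level2)
  df <- ifelse(term_lvl == "level2", G - p2 - 1, N - G - p1)
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df)

  vc <- lme4::VarCorr(fit)
  vg <- vc[[spec$group]]
  var_u0 <- vg["(Intercept)", "(Intercept)"]
  slope_tbl <- tibble::tibble(feature = character(), var_u1 = numeric(),
                              cov_u01 = numeric())
  if (length(spec$slopes)) {
    slope_tbl <- tibble::tibble(
      feature = spec$slopes,
      var_u1 = vg[cbind(spec$slopes, spec$slopes)],
      cov_u01 = vg["(Intercept)", spec$slopes]
    )
  }
  var_e <- attr(vc, "sc")^2

  ll <- as.numeric(logLik(fit))
  n_params <- length(est) + 1L + 1L +  # fixed + intercept variance + residual
    2L * length(spec$slopes)           # slope variance + covariance each

  structure(list(
    coefficients = tibble::tibble(term = terms, estimate = unname(est),
                                  se = unname(se), df = unname(df),
                                  t = unname(tval), p = unname(pval),
                                  level = unname(term_lvl)),
    varcomp = list(var_u0 = unname(var_u0), var_e = unname(var_e),
                   slopes = slope_tbl),
    logLik = ll, deviance = -2 * ll,
    n_obs = N, n_groups = G, n_params = n_params, n_dropped = n_dropped,
    spec = spec, model = fit,
    row_key = which(ok)
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-level LMM (%s): %s | %d obs in %d groups\n",
              x$spec$method, x$spec$response, x$n_obs, x$n_groups))
  print(as.data.frame(x$coefficients), digits = digits)
  cat(sprintf("Variance components: between-shift %0.3f, residual %0.3f",
              x$varcomp$var_u0, x$varcomp$var_e))
  if (nrow(x$varcomp$slopes)) {
    cat(sprintf(", slope (%s) %0.3f",
                x$varcomp$slopes$feature[1], x$varcomp$slopes$var_u1[1]))
  }
  cat(sprintf("\nDeviance (-2 logLik): %0.2f\n", x$deviance))
  invisible(x)
}

is_null_model <- function(fit) {
  length(spec_fixed_terms(fit$spec)) == 0 && length(fit$spec$slopes) == 0
}

#' Intraclass correlation from an intercept-only fit
#'
#' The proportion of total outcome variance lying between shifts,
#' `var_u0 / (var_u0 + var_e)`, from the null (intercept + random intercept)
#' model.
#'
#' @param fit An intercept-only `lmm_fit`.
#' @return ICC in `[0, 1]`.
#' @export
icc <- function(fit) {
  if (!is_null_model(fit)) {
    stop("ICC is defined for the intercept-only model; fit has predictors")
  }
  v <- fit$varcomp
  v$var_u0 / (v$var_u0 + v$var_e)
}

#' Group-mean reliability
#'
#' Spearman-Brown-style reliability of the shift mean rating: the average
#' over shifts of `var_u0 / (var_u0 + var_e / n_j)`, where `n_j` is the
#' number of rated segments in shift `j`.
#'
#' @param fit An intercept-only `lmm_fit`.
#' @param group_sizes Optional integer vector of group sizes; defaults to
#'   the sizes observed in the fit.
#' @return Reliability in `[0, 1]`.
#' @export
group_mean_reliability <- function(fit, group_sizes = NULL) {
  if (!is_null_model(fit)) {
    stop("group-mean reliability is defined for the intercept-only model")
  }
  if (is.null(group_sizes)) {
    group_sizes <- as.integer(table(fit$model@frame[[fit$spec$group]]))
  }
  if (any(group_sizes == 0)) {
    warning("excluding empty groups from reliability")
    group_sizes <- group_sizes[group_sizes > 0]
  }
  v <- fit$varcomp
  mean(v$var_u0 / (v$var_u0 + v$var_e / group_sizes))
}

#' Level-specific pseudo-R-squared
#'
#' Proportional reduction in each variance component of `fit` relative to
#' `reference`: within-shift `R2 = (var_e_ref - var_e_fit) / var_e_ref`,
#' between-shift analogously on the intercept variance, and (when both fits
#' carry the same random slope) the slope-variation analogue. Negative
#' values are reported as computed: a variance component can rise when the
#' model changes.
#'
#' @param fit,reference `lmm_fit` objects fitted to identical rows.
#' @return List with `r2_within`, `r2_between`, and `r2_slope` (the latter
#'   `NULL` unless both fits share a random slope feature).
#' @export
pseudo_r2 <- function(fit, reference) {
  if (fit$n_obs != reference$n_obs ||
      !identical(fit$row_key, reference$row_key)) {
    stop("pseudo-R2 requires fits on identical rows")
  }
  out <- list(
    r2_within = (reference$varcomp$var_e - fit$varcomp$var_e) /
      reference$varcomp$var_e,
    r2_between = (reference$varcomp$var_u0 - fit$varcomp$var_u0) /
      reference$varcomp$var_u0,
    r2_slope = NULL
  )
  shared <- intersect(fit$varcomp$slopes$feature,
                      reference$varcomp$slopes$feature)
  if (length(shared)) {
    f <- shared[1]
    v_ref <- reference$varcomp$slopes$var_u1[
      reference$varcomp$slopes$feature == f]
    v_fit <- fit$varcomp$slopes$var_u1[fit$varcomp$slopes$feature == f]
    out$r2_slope <- setNames((v_ref - v_fit) / v_ref, f)
  }
  out
}

#' Likelihood-ratio test between nested ML fits
#'
#' `chi2 = deviance_reduced - deviance_full` on `df` equal to the parameter
#' count difference (fixed effects plus variance/covariance parameters).
#' Both fits must be ML fits on identical rows; a meaningfully negative
#' statistic signals non-nesting or a convergence failure and is an error.
#'
#' @param fit_full,fit_reduced `lmm_fit` objects (the reduced fit may also
#'   be a pooled OLS null from [fit_pooled_null()]).
#' @return List with `chisq`, `df`, `p`.
#' @export
lr_test <- function(fit_full, fit_reduced) {
  for (f in list(fit_full, fit_reduced)) {
    if (inherits(f, "lmm_fit") && !identical(f$spec$method, "ML")) {
      stop("likelihood-ratio tests require ML fits")
    }
  }
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop("likelihood-ratio test requires fits on identical rows")
  }
  chisq <- fit_reduced$deviance - fit_full$deviance
  if (chisq < -1e-6) {
    stop("negative likelihood-ratio statistic: models are not nested ",
         "or a fit failed to converge")
  }
  chisq <- max(chisq, 0)
  df <- fit_full$n_params - fit_reduced$n_params
  p <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else
    if (chisq < 1e-8) 1 else NA_real_
  list(chisq = chisq, df = df, p = p)
}

#' Pooled (no-grouping) null model
#'
#' An intercept-only ordinary least-squares fit, used as the reference when
#' testing whether the shift grouping structure itself improves fit.
#'
#' @param data Analysis table.
#' @param response Response column name.
#' @return A minimal fit object with `deviance`, `logLik`, `n_obs`,
#'   `n_params` comparable in [lr_test()].
#' @export
fit_pooled_null <- function(data, response) {
  y <- data[[response]]
  y <- y[!is.na(y)]
  m <- lm(y ~ 1)
  ll <- as.numeric(logLik(m))
  list(deviance = -2 * ll, logLik = ll, n_obs = length(y), n_params = 2L,
       response = response)
}
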