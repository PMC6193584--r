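#' Elastic-net configuration
#'
#' Settings for the penalised screening stage. The penalty mixing parameter
#' `alpha` blends the lasso (`alpha = 1`) and ridge (`alpha = 0`) penalties;
#' the default 0.9 weights the lasso heavily so that screening is sparse but
#' correlated predictors are not forced to a single survivor.
#'
#' @param alpha Penalty mixing parameter in `[0, 1]`.
#' @param nlambda Number of points on the log-spaced penalty grid.
#' @param lambda_min_ratio Smallest grid value as a fraction of the largest;
#'   defaults to `1e-4` when `n > p` and `0.01` otherwise.
#' @param lambda Optional explicit decreasing penalty sequence (overrides the
#'   grid settings).
#' @param nfolds Number of cross-validation folds.
#' @param fold_seed Seed controlling the fold assignment.
#' @param tol Coordinate-descent convergence tolerance (largest absolute
#'   coefficient change in one full cycle).
#' @param maxit Maximum coordinate-descent cycles per penalty value.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.9, nlambda = 100, lambda_min_ratio = NULL,
                        lambda = NULL, nfolds = 10, fold_seed = 1L,
                        tol = 1e-5, maxit = 100000L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1)
  stopifnot(nfolds >= 2)
  if (!is.null(lambda)) {
    stopifnot(all(lambda >= 0))
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  structure(list(alpha = alpha, nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio, lambda = lambda,
                 nfolds = as.integer(nfolds), fold_seed = as.integer(fold_seed),
                 tol = tol, maxit = as.integer(maxit)),
            class = "enet_config")
}

enet_lambda_grid <- function(X, y, config) {
  if (anyNA(X) || anyNA(y)) {
    stop("the elastic net requires complete data; drop or impute missing ",
         "values first")
  }
  n <- nrow(X)
  p <- ncol(X)
  # alpha = 0 has no finite null threshold; use a small alpha for the grid,
  # as is conventional, so ridge paths still start from heavy shrinkage.
  a <- max(config$alpha, 1e-3)
  lambda_max <- max(abs(crossprod(X, y))) / (n * a)
  ratio <- config$lambda_min_ratio
  if (is.null(ratio)) ratio <- if (n > p) 1e-4 else 1e-2
  exp(seq(log(lambda_max), log(lambda_max * ratio),
          length.out = config$nlambda))
}

#' Elastic-net coefficient path
#'
#' Solves `(1/2n) ||y - X b||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)`
#' over a decreasing penalty sequence by cyclic coordinate descent with warm
#' starts. No intercept is fitted: `X` is expected column-centred (and usually
#' scaled) and `y` centred, as produced by [standardize()].
#'
#' @param X Numeric predictor matrix with column names.
#' @param y Numeric response vector, centred.
#' @param config An [enet_config()].
#' @return An object of class `enet_path` with elements `lambda`, `beta`
#'   (p x nlambda matrix), `df` (non-zero count per penalty), `converged`,
#'   `iters`, and `alpha`.
#' @export
elastic_net_path <- function(X, y, config = enet_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  lambda <- config$lambda %||% enet_lambda_grid(X, y, config)
  fit <- enet_cd_path(crossprod(X), drop(crossprod(X, y)), n, lambda,
                      config$alpha, config$tol, config$maxit)
  beta <- fit$beta
  rownames(beta) <- colnames(X)
  if (!all(fit$converged)) {
    warning(sprintf("coordinate descent did not converge at %d of %d penalty values",
                    sum(!fit$converged), length(lambda)))
  }
  structure(list(lambda = lambda, beta = beta,
                 df = colSums(beta != 0), converged = fit$converged,
                 iters = fit$iters, alpha = config$alpha),
            class = "enet_path")
}

#' @export
print.enet_path <- function(x, ...) {
  cat(sprintf("Elastic-net path: %d predictors, %d penalty values (alpha = %.2f)\n",
              nrow(x$beta), length(x$lambda), x$alpha))
  cat(sprintf("  lambda range [%.4g, %.4g]; df range [%d, %d]\n",
              min(x$lambda), max(x$lambda), min(x$df), max(x$df)))
  invisible(x)
}

#' Predictions from an elastic-net path
#'
#' @param object An `enet_path`.
#' @param newx Matrix of predictors in the same column order as the fit.
#' @param ... Unused.
#' @return Matrix of fitted values, one column per penalty value.
#' @export
predict.enet_path <- function(object, newx, ...) {
  as.matrix(newx) %*% object$beta
}

#' Coefficients at one penalty value
#'
#' @param object An `enet_path`.
#' @param lambda Penalty value; the nearest grid point is used.
#' @param ... Unused.
#' @return Named numeric vector of coefficients.
#' @export
coef.enet_path <- function(object, lambda = min(object$lambda), ...) {
  i <- which.min(abs(object$lambda - lambda))
  setNames(object$beta[, i], rownames(object$beta))
}

#' Cross-validated elastic net
#'
#' K-fold cross-validation of the elastic-net path. The penalty grid is
#' computed once from the full data; each training fold is fitted over that
#' grid and mean squared error is evaluated on the held-out fold. Fold
#' assignment is reproducible under `config$fold_seed`.
#'
#' @inheritParams elastic_net_path
#' @return An object of class `enet_cv` with the full-data `path`, `lambda`,
#'   `cvm` (mean CV error), `cvsd` (standard error over folds), `lambda_min`,
#'   and `lambda_lenient` (see Details).
#' @details `lambda_lenient` is the smallest penalty whose CV error is within
#'   one standard error of the minimum, i.e. the least-shrinkage end of the
#'   near-optimal plateau. It is used as the deliberately lenient first-stage
#'   penalty in [screen_interactions()] so that potentially important
#'   predictors are not discarded before the clustered modelling stage.
#' @export
cross_validate <- function(X, y, config = enet_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (config$nfolds > n) {
    stop("number of folds exceeds the number of observations")
  }
  lambda <- config$lambda %||% enet_lambda_grid(X, y, config)
  cfg <- config
  cfg$lambda <- lambda

  set.seed(config$fold_seed)
  folds <- sample(rep_len(seq_len(config$nfolds), n))

  mse <- matrix(NA_real_, config$nfolds, length(lambda))
  for (k in seq_len(config$nfolds)) {
    test <- folds == k
    fit_k <- elastic_net_path(X[!test, , drop = FALSE], y[!test], cfg)
    pred <- predict(fit_k, X[test, , drop = FALSE])
    mse[k, ] <- colMeans((y[test] - pred)^2)
  }
  cvm <- colMeans(mse)
  cvsd <- apply(mse, 2, sd) / sqrt(config$nfolds)
  i_min <- which.min(cvm)
  lenient <- lambda[max(which(cvm <= cvm[i_min] + cvsd[i_min]))]

  structure(list(path = elastic_net_path(X, y, cfg), lambda = lambda,
                 cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda[i_min], lambda_lenient = lenient,
                 nfolds = config$nfolds, fold_seed = config$fold_seed),
            class = "enet_cv")
}

#' @export
print.enet_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated elastic net\n", x$nfolds))
  cat(sprintf("  lambda_min = %.4g (CV MSE %.4g), lambda_lenient = %.4g\n",
              x$lambda_min, min(x$cvm), x$lambda_lenient))
  cat(sprintf("  selected at lambda_min: %d predictors\n",
              sum(coef(x$path, x$lambda_min) != 0)))
  invisible(x)
}

#' Two-stage hierarchical screen of main effects and pairwise interactions
#'
#' Stage one runs a cross-validated elastic net on the candidate main effects
#' and keeps every predictor that is non-zero at a lenient penalty (the
#' least-shrinkage penalty within one standard error of the cross-validation
#' minimum). Stage two refits a cross-validated elastic net on the stage-one
#' survivors together with all pairwise products among them, and retains the
#' terms that are non-zero at `lambda_min`. Because products are only formed
#' between survivors, every retained interaction has both parents available
#' downstream (strong hierarchy by construction). Rows are treated as
#' exchangeable: clustering is deliberately ignored at this screening stage
#' and handled later by the multilevel models.
#'
#' @inheritParams elastic_net_path
#' @param lenient Use the lenient stage-one penalty (default). With `FALSE`,
#'   stage one selects at `lambda_min`.
#' @return A list of class `selection_result`: `main_effects` (character),
#'   `interactions` (two-column character matrix of parent pairs),
#'   `stage1`/`stage2` (`enet_cv` objects; `stage2` `NULL` when fewer than two
#'   survivors), and `survivors` (stage-one retained set).
#' @export
screen_interactions <- function(X, y, config = enet_config(), lenient = TRUE) {
  X <- as.matrix(X)
  cv1 <- cross_validate(X, y, config)
  lam1 <- cv1$lambda_min
  if (lenient) {
    # least-shrinkage penalty within one SE of the CV minimum, but bounded:
    # leniency is relative to the CV-optimal support (at most about twice
    # its size), so a flat CV curve - e.g. a pure-noise response - cannot
    # admit the whole pool
    i_min <- which(cv1$lambda == cv1$lambda_min)[1]
    support <- cv1$path$df
    cap <- 2 * support[i_min] + 5
    band <- which(cv1$cvm <= cv1$cvm[i_min] + cv1$cvsd[i_min] &
                    support <= cap)
    if (length(band)) lam1 <- cv1$lambda[max(band)]
  }
  survivors <- names(which(coef(cv1$path, lam1) != 0))

  interactions <- matrix(character(), 0, 2,
                         dimnames = list(NULL, c("parent1", "parent2")))
  mains <- survivors
  cv2 <- NULL
  if (length(survivors) >= 2) {
    Xs <- X[, survivors, drop = FALSE]
    pairs <- utils::combn(survivors, 2)
    prods <- apply(pairs, 2, function(pr) Xs[, pr[1]] * Xs[, pr[2]])
    colnames(prods) <- apply(pairs, 2, paste, collapse = ":")
    keep <- apply(prods, 2, sd) > 0
    prods <- scale(prods[, keep, drop = FALSE])
    X2 <- cbind(Xs, prods)
    cfg2 <- config
    cfg2$fold_seed <- config$fold_seed + 1L
    cv2 <- cross_validate(X2, y, cfg2)
    sel2 <- names(which(coef(cv2$path, cv2$lambda_min) != 0))
    int_names <- sel2[grepl(":", sel2, fixed = TRUE)]
    mains <- sel2[!grepl(":", sel2, fixed = TRUE)]
    if (length(int_names)) {
      interactions <- do.call(rbind, strsplit(int_names, ":", fixed = TRUE))
      colnames(interactions) <- c("parent1", "parent2")
      # strong hierarchy: parents of every retained product are carried forward
      mains <- union(mains, as.vector(interactions))
    }
  } else if (length(survivors) == 1) {
    sel <- names(which(coef(cv1$path, cv1$lambda_min) != 0))
    mains <- sel
  }

  structure(list(main_effects = mains, interactions = interactions,
                 survivors = survivors, stage1 = cv1, stage2 = cv2),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Elastic-net screen: %d stage-1 survivors, %d main effects, %d interaction pairs\n",
              length(x$survivors), length(x$main_effects), nrow(x$interactions)))
  if (length(x$main_effects)) {
    cat("  mains:", paste(x$main_effects, collapse = ", "), "\n")
  }
  if (nrow(x$interactions)) {
    cat("  pairs:", paste(apply(x$interactions, 1, paste, collapse = " x "),
                          collapse = "; "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
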