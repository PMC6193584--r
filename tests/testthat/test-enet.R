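# exact settings for closed-form comparisons
tight <- function(...) enet_config(..., tol = 1e-10)

test_that("penalties above the null threshold zero every coefficient", {
  set.seed(1)
  X <- scale(matrix(rnorm(200), 40, 5))
  y <- drop(scale(rnorm(40)))
  lam_max <- max(abs(crossprod(X, y))) / (40 * 0.9)
  path <- elastic_net_path(X, y, tight(alpha = 0.9,
                                       lambda = c(2 * lam_max,
                                                  1.01 * lam_max)))
  expect_true(all(path$beta == 0))
})

test_that("orthonormal-design lasso is exact soft thresholding", {
  n <- 8
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:2]
  X <- Q * sqrt(n)                      # X'X = n I
  y <- 0.5 * X[, 1]                     # x1'y / n = 0.5, x2'y / n = 0
  path <- elastic_net_path(X, y, tight(alpha = 1, lambda = 0.2))
  expect_equal(unname(path$beta[, 1]), c(0.3, 0), tolerance = 1e-8)
})

test_that("an unpenalised fit solves least squares, ridge matches its closed form", {
  set.seed(2)
  n <- 60; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p))
  y <- drop(X %*% c(1, -0.5, 0, 0.3, 0) + rnorm(n, 0, 0.5))
  y <- y - mean(y)

  ols <- solve(crossprod(X), crossprod(X, y))
  path0 <- elastic_net_path(X, y, tight(alpha = 0.9, lambda = 0))
  expect_equal(unname(path0$beta[, 1]), drop(ols), tolerance = 1e-7)

  for (lam in c(0.05, 0.5)) {
    ridge <- solve(crossprod(X) + n * lam * diag(p), crossprod(X, y))
    pr <- elastic_net_path(X, y, tight(alpha = 0, lambda = lam))
    expect_equal(unname(pr$beta[, 1]), drop(ridge), tolerance = 1e-7)
  }
})

test_that("coordinate descent agrees with an independent solver on random instances", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  for (i in 1:50) {
    n <- sample(20:50, 1); p <- sample(3:10, 1)
    X <- scale(matrix(rnorm(n * p), n, p))
    beta <- rnorm(p) * rbinom(p, 1, 0.5)
    # the oracle standardises the response internally by its 1/n standard
    # deviation; hand it a response that is already unit on that scale so
    # both programs solve the identical objective
    y <- drop(X %*% beta + rnorm(n)); y <- y - mean(y)
    y <- y / sqrt(mean(y^2))
    a <- sample(c(0.3, 0.9, 1), 1)
    cfg <- tight(alpha = a, nlambda = 30)
    path <- elastic_net_path(X, y, cfg)
    g <- glmnet::glmnet(X, y, alpha = a, lambda = path$lambda,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
    expect_lt(max(abs(as.matrix(g$beta) - path$beta)), 1e-6)
  }
})

test_that("the active set shrinks as the penalty grows, continuously", {
  set.seed(4)
  X <- scale(matrix(rnorm(100 * 8), 100, 8))
  y <- drop(X %*% c(2, -1, 0.5, rep(0, 5)) + rnorm(100)); y <- y - mean(y)
  path <- elastic_net_path(X, y, tight(alpha = 0.9))
  df <- path$df
  expect_equal(df[1], 0)                       # grid starts at lambda_max
  expect_equal(df[length(df)], 8)
  # weakly decreasing in lambda, allowing small jitter for the mixed penalty
  expect_true(all(diff(df) >= -1))
  jumps <- apply(abs(path$beta[, -1] - path$beta[, -ncol(path$beta)]), 2, max)
  expect_lt(max(jumps), 0.25 * max(abs(path$beta)))
})

test_that("cross-validation is fold-seed deterministic and rejects k > n", {
  set.seed(5)
  X <- scale(matrix(rnorm(50 * 4), 50, 4))
  y <- drop(scale(rnorm(50)))
  cv1 <- cross_validate(X, y, enet_config(fold_seed = 9))
  cv2 <- cross_validate(X, y, enet_config(fold_seed = 9))
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  expect_identical(cv1$cvm, cv2$cvm)
  expect_error(cross_validate(X[1:5, ], y[1:5], enet_config(nfolds = 10)),
               "folds")
  # lenient penalty sits on the less-shrinkage (smaller lambda) side
  expect_lte(cv1$lambda_lenient, cv1$lambda_min)
})

test_that("a planted two-variable signal is retained at lambda_min", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 200
    X <- scale(matrix(rnorm(n * 8), n, 8))
    colnames(X) <- paste0("x", 1:8)
    y <- drop(2 * X[, 1] - X[, 2] + rnorm(n)); y <- y - mean(y)
    cv <- cross_validate(X, y, enet_config(fold_seed = s))
    sel <- names(which(coef(cv$path, cv$lambda_min) != 0))
    if (all(c("x1", "x2") %in% sel)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("pure noise yields a near-empty selection at lambda_min", {
  sizes <- vapply(1:10, function(s) {
    set.seed(s + 300)
    X <- scale(matrix(rnorm(150 * 12), 150, 12))
    y <- drop(scale(rnorm(150)))
    cv <- cross_validate(X, y, enet_config(fold_seed = s))
    sum(coef(cv$path, cv$lambda_min) != 0)
  }, numeric(1))
  expect_lt(mean(sizes), 4)       # on average a third of the pool at most
  expect_gte(sum(sizes <= 2), 5)  # and usually (almost) nothing
})

test_that("the hierarchical screen finds a planted product interaction", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s + 1000)
    n <- 500
    raw <- matrix(rnorm(n * 6, mean = 1), n, 6)  # nonzero means: the product
    colnames(raw) <- paste0("x", 1:6)            # leaks into the main effects
    y <- raw[, 1] * raw[, 2] + rnorm(n, 0, 1)
    X <- scale(raw); y <- y - mean(y)
    sel <- screen_interactions(X, y, enet_config(fold_seed = s))
    pair_hit <- nrow(sel$interactions) > 0 &&
      any(apply(sel$interactions, 1, function(pr)
        setequal(pr, c("x1", "x2"))))
    if (pair_hit) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("an additive truth produces fewer interactions than a product truth", {
  n_int <- function(s, additive) {
    set.seed(s + 2000)
    n <- 300
    raw <- matrix(rnorm(n * 5, mean = 1), n, 5)
    colnames(raw) <- paste0("x", 1:5)
    y <- if (additive) raw[, 1] + raw[, 2] + rnorm(n) else
      raw[, 1] * raw[, 2] + rnorm(n)
    sel <- screen_interactions(scale(raw), y - mean(y),
                               enet_config(fold_seed = s))
    nrow(sel$interactions)
  }
  add <- vapply(1:20, n_int, numeric(1), additive = TRUE)
  prod <- vapply(1:20, n_int, numeric(1), additive = FALSE)
  expect_lt(mean(add), mean(prod))
})

test_that("a single candidate feature yields no interaction pairs", {
  set.seed(6)
  n <- 200
  X <- scale(matrix(rnorm(n), n, 1))
  colnames(X) <- "x1"
  y <- drop(3 * X[, 1] + rnorm(n, 0, 0.3)); y <- y - mean(y)
  sel <- screen_interactions(X, y, enet_config(fold_seed = 1))
  expect_equal(nrow(sel$interactions), 0)
  expect_equal(sel$main_effects, "x1")
})
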