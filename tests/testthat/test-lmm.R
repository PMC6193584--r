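test_that("balanced one-way fits match the closed-form ANOVA ML estimates", {
  set.seed(10)
  for (i in 1:100) {
    G <- sample(4:10, 1); m <- sample(2:5, 1)
    v_u <- runif(1, 0.2, 2); v_e <- runif(1, 0.2, 2)
    dat <- make_clustered(G, m, var_u0 = v_u, var_e = v_e, seed = 1000 + i)
    fit <- fit_lmm(lmm_spec("y"), dat)
    oracle <- anova_ml(dat$y, dat$shift_id)
    expect_equal(fit$varcomp$var_e, unname(oracle["var_e"]),
                 tolerance = 1e-6)
    expect_equal(fit$varcomp$var_u0, unname(oracle["var_u0"]),
                 tolerance = 1e-6)
  }
})

test_that("identical group means put the intercept variance on the boundary", {
  dat <- tibble::tibble(shift_id = rep(c("a", "b", "c", "d"), each = 3),
                        y = rep(c(-1, 0, 1), 4))
  fit <- fit_lmm(lmm_spec("y"), dat)
  expect_equal(fit$varcomp$var_u0, 0, tolerance = 1e-8)
})

test_that("containment degrees of freedom follow the level of each term", {
  set.seed(11)
  G <- 35
  m <- c(rep(3, 19), rep(2, 16))         # 89 segments across 35 shifts
  dat <- tibble::tibble(
    shift_id = rep(sprintf("S%02d", 1:G), m),
    x1 = rnorm(sum(m)), x2 = rnorm(sum(m)), x3 = rnorm(sum(m)))
  z <- rnorm(G)
  dat$z1 <- z[match(dat$shift_id, sprintf("S%02d", 1:G))]
  dat$y <- rnorm(sum(m))
  expect_equal(nrow(dat), 89)

  spec <- lmm_spec("y", level1 = c("x1", "x2", "x3"),
                   level1_products = "x1:x2", level2 = "z1")
  fit <- fit_lmm(spec, dat)
  tab <- fit$coefficients
  # four Level-1 terms (3 mains + 1 product): df = 89 - 35 - 4 = 50
  expect_true(all(tab$df[tab$term %in% c("x1", "x2", "x3", "x1:x2")] == 50))
  expect_equal(tab$df[tab$term == "(Intercept)"], 50)
  # one Level-2 term: df = 35 - 1 - 1 = 33
  expect_equal(tab$df[tab$term == "z1"], 33)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_equal(fit$deviance, -2 * fit$logLik)
})

test_that("a collinear design is refused with the offending terms named", {
  dat <- make_clustered(10, 3, beta = c(x1 = 1), seed = 3)
  dat$x2 <- dat$x1
  spec <- lmm_spec("y", level1 = c("x1", "x2"))
  expect_error(fit_lmm(spec, dat), "collinear.*x2")
})

test_that("hierarchy violations are rejected at specification time", {
  expect_error(lmm_spec("y", level1 = "a", level1_products = "a:b"),
               "hierarchy")
  expect_error(lmm_spec("y", level2 = "z", cross = "z:x"), "hierarchy")
  expect_error(lmm_spec("y", level1 = "a", slopes = "b"), "slope")
})

test_that("the ICC is the between-shift variance share of the null model", {
  dat <- make_clustered(150, 4, var_u0 = 1, var_e = 1, seed = 5)
  fit <- fit_lmm(lmm_spec("y"), dat)
  v <- fit$varcomp
  expect_equal(icc(fit), v$var_u0 / (v$var_u0 + v$var_e))
  expect_lt(abs(icc(fit) - 0.5), 0.12)
  with_pred <- fit_lmm(lmm_spec("y", level1 = "x1"),
                       make_clustered(20, 3, beta = c(x1 = 1), seed = 6))
  expect_error(icc(with_pred), "intercept-only")
  expect_error(group_mean_reliability(with_pred), "intercept-only")
})

test_that("group-mean reliability follows the Spearman-Brown form", {
  dat <- make_clustered(40, 4, var_u0 = 1, var_e = 1, seed = 7)
  fit <- fit_lmm(lmm_spec("y"), dat)
  v <- fit$varcomp
  # equal variance components, n_j = 4 -> 1 / (1 + 1/4) = 0.8
  expect_equal(group_mean_reliability(fit, group_sizes = rep(4L, 40)),
               v$var_u0 / (v$var_u0 + v$var_e / 4))
  # reliability tends to 1 as groups grow
  expect_gt(group_mean_reliability(fit, group_sizes = rep(10000L, 40)), 0.999)
  expect_warning(r <- group_mean_reliability(fit, group_sizes = c(rep(4L, 39),
                                                                  0L)),
                 "empty")
  expect_lte(r, 1)
  # reliability is never below the ICC
  expect_gte(group_mean_reliability(fit), icc(fit))
})

test_that("pseudo-R2 is the proportional reduction in each variance component", {
  dat <- make_clustered(40, 3, beta = c(x1 = 1), var_u0 = 0.8, var_e = 0.6,
                        seed = 8)
  null <- fit_lmm(lmm_spec("y"), dat)
  full <- fit_lmm(lmm_spec("y", level1 = "x1"), dat)
  r2 <- pseudo_r2(full, null)
  expect_equal(r2$r2_within,
               (null$varcomp$var_e - full$varcomp$var_e) / null$varcomp$var_e)
  expect_equal(r2$r2_between,
               (null$varcomp$var_u0 - full$varcomp$var_u0) /
                 null$varcomp$var_u0)
  same <- pseudo_r2(null, null)
  expect_equal(same$r2_within, 0)
  expect_equal(same$r2_between, 0)
  other <- fit_lmm(lmm_spec("y"), dat[1:90, ])
  expect_error(pseudo_r2(other, null), "identical rows")
})

test_that("likelihood-ratio tests compare deviances with the parameter-count df", {
  dat <- make_clustered(30, 3, beta = c(x1 = 0.8, x2 = 0), seed = 9)
  null <- fit_lmm(lmm_spec("y"), dat)
  full <- fit_lmm(lmm_spec("y", level1 = c("x1", "x2")), dat)
  lt <- lr_test(full, null)
  expect_equal(lt$chisq, null$deviance - full$deviance)
  expect_equal(lt$df, 2)
  expect_equal(lt$p, pchisq(lt$chisq, 2, lower.tail = FALSE))

  ident <- lr_test(null, null)
  expect_equal(ident$chisq, 0)
  expect_equal(ident$p, 1)

  # swapping full and reduced signals non-nesting through the negative statistic
  expect_error(lr_test(null, full), "negative|nested")

  reml <- fit_lmm(lmm_spec("y", method = "REML"), dat)
  expect_error(lr_test(full, reml), "ML")
})

test_that("deviance never increases when a fixed term is added under ML", {
  set.seed(12)
  for (i in 1:20) {
    dat <- make_clustered(15, 3, beta = c(x1 = runif(1, 0, 1)),
                          seed = 400 + i)
    dat$x2 <- rnorm(nrow(dat))
    f1 <- fit_lmm(lmm_spec("y", level1 = "x1"), dat)
    f2 <- fit_lmm(lmm_spec("y", level1 = c("x1", "x2")), dat)
    expect_lte(f2$deviance, f1$deviance + 1e-6)
  }
})

test_that("the null-model LR statistic is approximately chi-squared(1)", {
  set.seed(13)
  stats <- vapply(1:300, function(i) {
    dat <- make_clustered(20, 3, beta = c(x1 = 0), var_u0 = 0.5,
                          var_e = 0.5, seed = 5000 + i)
    f0 <- fit_lmm(lmm_spec("y"), dat)
    f1 <- fit_lmm(lmm_spec("y", level1 = "x1"), dat)
    lr_test(f1, f0)$chisq
  }, numeric(1))
  expect_equal(mean(stats), 1, tolerance = 0.25)
  expect_lt(abs(mean(stats > qchisq(0.95, 1)) - 0.05), 0.04)
})

test_that("random-slope fits expose the slope variance and covariance", {
  set.seed(14)
  G <- 80; m <- 4
  dat <- tibble::tibble(shift_id = rep(sprintf("G%02d", 1:G), each = m),
                        x1 = rnorm(G * m))
  u0 <- rnorm(G, 0, 1); u1 <- rnorm(G, 0, 0.7)
  idx <- rep(1:G, each = m)
  dat$y <- 0.5 * dat$x1 + u0[idx] + u1[idx] * dat$x1 + rnorm(G * m, 0, 0.5)
  fit <- fit_lmm(lmm_spec("y", level1 = "x1", slopes = "x1"), dat)
  expect_equal(nrow(fit$varcomp$slopes), 1)
  expect_equal(fit$varcomp$slopes$feature, "x1")
  expect_equal(fit$varcomp$slopes$var_u1, 0.49, tolerance = 0.35)
  expect_equal(fit$n_params, 2 + 2 + 2)  # 2 fixed, u0+resid, slope var+cov
})
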