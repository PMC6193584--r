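# Independent brute-force oracles used across the suite.

# burstiness computed step by step from its definition
brute_burstiness <- function(times) {
  times <- sort(times)
  gaps <- times[-1] - times[-length(times)]
  if (length(gaps) < 2) return(NA_real_)
  mu <- sum(gaps) / length(gaps)
  s <- sqrt(sum((gaps - mu)^2) / (length(gaps) - 1))
  (s - mu) / (s + mu)
}

# transition entropy by explicit pair enumeration
brute_entropy <- function(zones) {
  merged <- zones[1]
  for (z in zones[-1]) if (z != merged[length(merged)]) merged <- c(merged, z)
  if (length(merged) < 2) return(0)
  pairs <- character()
  for (i in seq_len(length(merged) - 1)) {
    pairs <- c(pairs, paste0(merged[i], "->", merged[i + 1]))
  }
  h <- 0
  for (pr in unique(pairs)) {
    p <- sum(pairs == pr) / length(pairs)
    h <- h - p * log2(p)
  }
  h
}

# closed-form ML estimates for the balanced one-way random-effects model:
# residual variance SSW / (N - a); between variance (SSB/a - s2e) / n
anova_ml <- function(y, g) {
  means <- tapply(y, g, mean)
  n <- as.integer(table(g))
  stopifnot(length(unique(n)) == 1)
  n <- n[1]
  a <- length(means)
  ssw <- sum((y - means[g])^2)
  ssb <- n * sum((means - mean(y))^2)
  s2e <- ssw / (a * (n - 1))
  s2u <- (ssb / a - s2e) / n
  if (s2u < 0) {       # boundary: iid model, ML variance divides by N
    s2u <- 0
    s2e <- (ssw + ssb) / (a * n)
  }
  c(var_e = s2e, var_u0 = unname(s2u))
}

# z-scoring identical to the generator's internal standardisation
zscore_cols <- function(df, cols) {
  for (j in cols) {
    s <- sd(df[[j]], na.rm = TRUE)
    df[[j]] <- (df[[j]] - mean(df[[j]], na.rm = TRUE)) / ifelse(s > 0, s, 1)
  }
  df
}

# small balanced clustered dataset for model tests
make_clustered <- function(G = 20, m = 3, beta = numeric(), var_u0 = 0.5,
                           var_e = 0.5, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  dat <- tibble::tibble(shift_id = rep(sprintf("G%03d", 1:G), each = m))
  X <- matrix(rnorm(G * m * max(p, 1)), G * m)
  if (p > 0) {
    colnames(X) <- names(beta) %||% paste0("x", 1:p)
    for (j in 1:p) dat[[colnames(X)[j]]] <- X[, j]
  }
  u <- rnorm(G, 0, sqrt(var_u0))
  dat$y <- (if (p > 0) drop(X[, 1:p, drop = FALSE] %*% beta) else 0) +
    rep(u, each = m) + rnorm(G * m, 0, sqrt(var_e))
  dat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
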