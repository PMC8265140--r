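# Independent oracles and small fixture generators used across the suite.

# Definitional concentration-index oracle: fractional ranks by explicit
# per-individual summation (no sorting/cumsum machinery shared with the
# implementation), then 2/mu * weighted covariance.
brute_ci <- function(y, scores, w = rep(1, length(y))) {
  n <- length(y)
  wn <- w / sum(w)
  R <- numeric(n)
  for (i in seq_len(n)) {
    R[i] <- sum(wn[scores < scores[i]]) + sum(wn[scores == scores[i]]) / 2
  }
  mu <- sum(wn * y)
  Rbar <- sum(wn * R)
  2 / mu * sum(wn * (y - mu) * (R - Rbar))
}

# random small instance with positive outcome mean, duplicate scores allowed
random_instance <- function(n, binary = TRUE) {
  y <- if (binary) {
    v <- rbinom(n, 1, 0.4)
    if (sum(v) == 0) v[sample(n, 1)] <- 1
    v
  } else {
    rexp(n) + 0.1
  }
  list(
    y = y,
    scores = sample(seq_len(max(2, n %/% 2)), n, replace = TRUE) + 0,
    w = rexp(n) + 0.1
  )
}

# small config for fast end-to-end runs
tiny_config <- function(seed = 1, ...) {
  sim_config(n_clusters = 30, households_per_cluster = 12, seed = seed, ...)
}

# config with no planted covariate structure; wealth_effect overridable
null_config <- function(seed = 1, wealth_effect = 0, ...) {
  zero_coefs <- lapply(svyineq:::default_logit_coefs(), function(co) co * 0)
  sim_config(logit_intercept = 0, logit_coefs = zero_coefs,
             wealth_effect = wealth_effect, seed = seed, ...)
}

table4_fixture <- function() {
  path <- system.file("extdata", "decomp_table_nfhs4_men.csv",
                      package = "svyineq")
  read.csv(path, stringsAsFactors = FALSE)
}
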