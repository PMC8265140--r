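test_that("generation is deterministic given config and seed", {
  cfg <- tiny_config(seed = 99)
  d1 <- simulate_survey(cfg)
  d2 <- simulate_survey(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_survey(cfg, seed = 100)
  expect_false(identical(d1$anaemic, d3$anaemic))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(1234)
  a <- runif(1)
  set.seed(1234)
  invisible(simulate_survey(tiny_config(seed = 5)))
  expect_identical(runif(1), a)
})

test_that("invalid configurations are refused with the offending field named", {
  expect_error(sim_config(n_clusters = 0), "n_clusters")
  expect_error(sim_config(category_probs = list(bmi = c(a = .5, b = .6))),
               "category_probs")
  expect_error(sim_config(category_probs = list(bmi = c(a = -.1, b = 1.1))),
               "category_probs")
  expect_error(sim_config(category_probs = list(nonsense = c(a = 1))),
               "nonsense")
  expect_error(sim_config(weight_dispersion = -1), "weight_dispersion")
  expect_error(sim_config(logit_coefs = list(bmi = c(giant = 2))), "giant")
})

test_that("records satisfy the structural invariants", {
  d <- simulate_survey(tiny_config(seed = 3))
  expect_true(all(d$weight > 0))
  expect_true(all(d$anaemic %in% 0:1))
  # threshold consistency is exact, not approximate
  expect_identical(as.integer(d$haemoglobin < 13), d$anaemic)
  # wealth score is a household-level quantity
  spread <- tapply(d$wealth_score, d$household_id, function(s) diff(range(s)))
  expect_true(all(spread == 0))
  # household ids nest in cluster ids
  expect_true(all(tapply(d$cluster_id, d$household_id,
                         function(x) length(unique(x))) == 1))
})

test_that("covariate marginals match the configured probabilities", {
  cfg <- sim_config(n_clusters = 250, households_per_cluster = 40, seed = 17)
  d <- simulate_survey(cfg)
  expect_gte(nrow(d), 10000)
  n <- nrow(d)
  for (nm in c("age", "education", "bmi", "tobacco")) {
    p <- cfg$category_probs[[nm]]
    obs <- as.vector(prop.table(table(d[[nm]])))
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(obs - p) <= 3 * se + 1e-9),
                info = paste("marginal drift in", nm))
  }
})

test_that("null configuration yields ~50% prevalence and no inequality", {
  cfg <- null_config(seed = 8, n_clusters = 120, households_per_cluster = 30)
  d <- simulate_survey(cfg)
  n <- nrow(d)
  expect_lt(abs(mean(d$anaemic) - 0.5), 3 * sqrt(0.25 / n))
  ci <- concindex(d$anaemic, scores = d$wealth_score, weights = d$weight)
  expect_lt(abs(ci$C), 3 * 0.6 / sqrt(n))  # sd(C) ~ 1/sqrt(3n) for null binary
})

test_that("strongly negative wealth effects put more outcome in the bottom
           quintile", {
  cfg <- sim_config(seed = 13, wealth_effect = -0.6)
  d <- simulate_survey(cfg)
  expect_gte(nrow(d), 45000)
  prev <- tapply(seq_len(nrow(d)), d$wealth_quintile, function(i)
    weighted.mean(d$anaemic[i], d$weight[i]))
  expect_gt(prev[["1"]], prev[["5"]])
})

test_that("planted truth reports pro-poor inequality that flips with the
           effect sign and refuses tiny references", {
  cfg <- tiny_config(seed = 2)
  tr_neg <- planted_truth(cfg, n_reference = 20000)
  expect_lt(tr_neg$large_sample_ci, 0)
  expect_true(tr_neg$prevalence > 0 && tr_neg$prevalence < 1)

  cfg_pos <- tiny_config(seed = 2, wealth_effect = +0.28)
  tr_pos <- planted_truth(cfg_pos, n_reference = 20000)
  expect_gt(tr_pos$large_sample_ci, 0)

  expect_error(planted_truth(cfg, n_reference = 500), ">= 1000")
})

test_that("more negative wealth effects give non-increasing large-sample CI", {
  grid <- c(0, -0.3, -0.8)
  cis <- vapply(grid, function(b) {
    planted_truth(tiny_config(seed = 4, wealth_effect = b),
                  n_reference = 30000)$large_sample_ci
  }, numeric(1))
  expect_true(all(diff(cis) <= 0.01))  # non-increasing up to MC noise
})

test_that("survey and truth writers produce readable sidecar files", {
  cfg <- tiny_config(seed = 6)
  d <- simulate_survey(cfg)
  tr <- planted_truth(cfg, n_reference = 5000)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_survey(d, csv)
  write_truth(tr, cfg, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(d))
  expect_equal(back$wealth_score, d$wealth_score, tolerance = 1e-9)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$truth$large_sample_ci, tr$large_sample_ci,
               tolerance = 1e-12)
  expect_equal(meta$config$wealth_effect, cfg$wealth_effect)
  unlink(c(csv, js))
})
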