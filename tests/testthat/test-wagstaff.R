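test_that("saturated self-decomposition explains everything", {
  set.seed(101)
  y <- rbinom(50, 1, 0.4)
  y[1] <- 1
  sc <- rnorm(50)
  fit <- wagstaff(cbind(self = y), y = y, scores = sc)
  expect_equal(fit$table$coefficient, 1, tolerance = 1e-10)
  expect_equal(fit$table$mean, fit$mu, tolerance = 1e-12)
  expect_equal(fit$table$elasticity, 1, tolerance = 1e-10)
  expect_equal(fit$table$ci, fit$actual_ci, tolerance = 1e-10)
  expect_equal(fit$explained_ci, fit$actual_ci, tolerance = 1e-10)
  expect_equal(fit$residual, 0, tolerance = 1e-10)
  expect_equal(unname(percentage_contributions(fit)), 100, tolerance = 1e-8)
})

test_that("explained + residual = actual exactly, and the residual equals the
           generalized CI of the error", {
  set.seed(103)
  for (rep in 1:30) {
    n <- sample(20:80, 1)
    y <- rbinom(n, 1, 0.4); y[1] <- 1
    X <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n), c = rbinom(n, 1, 0.3))
    sc <- rnorm(n)
    w <- rexp(n) + 0.1
    fit <- wagstaff(X, y = y, scores = sc, weights = w)
    expect_equal(fit$explained_ci + fit$residual, fit$actual_ci,
                 tolerance = 1e-10)
    expect_equal(fit$residual, fit$residual_check, tolerance = 1e-8)
    # actual CI agrees with the standalone index on the same ranks
    expect_equal(fit$actual_ci,
                 concindex(y, scores = sc, weights = w)$C, tolerance = 1e-10)
  }
})

test_that("a regressor independent of outcome and wealth contributes ~0", {
  set.seed(107)
  n <- 10000
  sc <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 - 0.5 * sc))
  X <- cbind(wealthy = as.numeric(sc > 0), noise = rbinom(n, 1, 0.5))
  fit <- wagstaff(X, y = y, scores = sc)
  noise_contrib <- fit$table$contribution[fit$table$term == "noise"]
  expect_lt(abs(noise_contrib), 0.005)
})

test_that("adding an orthogonalized regressor leaves other contributions
           alone", {
  set.seed(109)
  n <- 400
  sc <- rnorm(n)
  x1 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + x1 - 0.4 * sc)); y[1] <- 1
  w <- rep(1, n)
  R <- fractional_rank(sc, w)
  # build z orthogonal (in the weighted inner product) to y, R, x1, intercept
  raw <- rnorm(n)
  z <- lm.fit(cbind(1, y, R, x1), raw)$residuals
  f1 <- wagstaff(cbind(x1 = x1), y = y, scores = sc, weights = w)
  f2 <- wagstaff(cbind(x1 = x1, z = z), y = y, scores = sc, weights = w)
  expect_equal(f2$table$contribution[f2$table$term == "x1"],
               f1$table$contribution[f1$table$term == "x1"],
               tolerance = 1e-8)
  expect_lt(abs(f2$table$contribution[f2$table$term == "z"]), 1e-8)
})

test_that("the formula interface dummy-codes factors against their reference
           and names collinear columns", {
  d <- data.frame(
    y = c(1, 0, 1, 0, 1, 1, 0, 0),
    g = factor(rep(c("ref", "hi"), 4), levels = c("ref", "hi")),
    s = c(3, 1, 4, 1, 5, 9, 2, 6)
  )
  fit <- wagstaff(y ~ g, data = d, scores = "s")
  expect_equal(fit$table$term, "ghi")
  expect_equal(fit$explained_ci + fit$residual, fit$actual_ci,
               tolerance = 1e-12)

  d$g2 <- d$g
  expect_error(wagstaff(y ~ g + g2, data = d, scores = "s"),
               "rank deficient.*g2")
  expect_error(wagstaff(y ~ g, data = transform(d, y = 0), scores = "s"),
               "zero mean")
})

test_that("percentage contributions honour the denominator choice and group
           totals partition correctly", {
  set.seed(113)
  n <- 500
  d <- data.frame(
    y = rbinom(n, 1, 0.3),
    g = factor(sample(c("a", "b", "c"), n, TRUE)),
    h = factor(sample(c("u", "v"), n, TRUE)),
    s = rnorm(n)
  )
  d$y[1] <- 1
  fit <- wagstaff(y ~ g + h, data = d, scores = "s")
  pe <- percentage_contributions(fit, "explained")
  expect_equal(sum(pe), 100, tolerance = 1e-8)
  pa <- percentage_contributions(fit, "actual")
  expect_equal(pa / pe, rep(fit$explained_ci / fit$actual_ci, length(pa)),
               ignore_attr = TRUE, tolerance = 1e-8)

  gt <- group_contributions(fit)
  expect_setequal(gt$group, c("g", "h"))
  expect_equal(sum(gt$pct), 100, tolerance = 1e-8)
  expect_equal(sum(gt$contribution), fit$explained_ci, tolerance = 1e-12)

  # custom groupings must partition the regressors
  expect_error(
    group_contributions(fit, grouping = list(A = c("gb", "gc"), B = "gb")),
    "two groups")
  expect_error(group_contributions(fit, grouping = list(A = "nope")),
               "unknown")
  expect_equal(group_contributions(fit, grouping = list(empty = character()))$
                 contribution, 0)
})

test_that("wealth dominates the decomposition when inequality is planted
           purely through wealth", {
  cfg <- null_config(seed = 11, wealth_effect = -0.5)
  d <- simulate_survey(cfg)
  expect_gte(nrow(d), 45000)
  d$wealth_quintile <- factor(d$wealth_quintile)
  fit <- wagstaff(anaemic ~ age + education + bmi + residence + region +
                    wealth_quintile,
                  data = d, scores = d$wealth_score, weights = d$weight)
  gt <- group_contributions(fit)
  wq <- abs(gt$pct[gt$group == "wealth_quintile"])
  expect_true(all(wq > abs(gt$pct[gt$group != "wealth_quintile"])))
})

test_that("model methods behave like a classic fit object", {
  d <- data.frame(
    y = c(1, 0, 1, 0, 1, 1, 0, 0),
    g = factor(rep(c("ref", "hi"), 4), levels = c("ref", "hi")),
    s = c(3, 1, 4, 2, 5, 9, 2, 6)
  )
  fit <- wagstaff(y ~ g, data = d, scores = "s")
  expect_named(coef(fit), c("(Intercept)", "ghi"))
  expect_length(residuals(fit), 8)
  expect_equal(unname(predict(fit, newdata = d)),
               unname(fit$fit$fitted.values), tolerance = 1e-12)
  expect_output(print(fit), "Actual CI")
  expect_output(print(summary(fit)), "Group totals")
})
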