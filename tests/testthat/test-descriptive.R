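test_that("prevalence tables reproduce degenerate strata exactly", {
  d <- data.frame(y = c(1, 1, 0, 0), g = c("A", "A", "B", "B"))
  t1 <- prevalence_by(d, "g", outcome = "y")
  expect_equal(t1$prevalence_pct, c(100, 0, 50))
  expect_equal(t1$sample_pct, c(50, 50, 100))

  d$w <- c(3, 1, 1, 3)
  t2 <- prevalence_by(d, "g", outcome = "y", weight = "w")
  expect_equal(t2$prevalence_pct, c(100, 0, 50))
  expect_equal(t2$sample_pct, c(50, 50, 100))
})

test_that("unknown covariates are reported with the available names", {
  d <- data.frame(y = 0:1, g = c("A", "B"))
  expect_error(prevalence_by(d, "nope", outcome = "y"), "available.*g")
})

test_that("chi-square matches direct O/E arithmetic and symmetry", {
  flat <- chi_square_independence(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  # all expected counts 15: X2 = 4 * 25/15 = 20/3
  m <- rbind(c(20, 10), c(10, 20))
  res <- chi_square_independence(m)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$df, 1)

  # invariant to row/column permutation
  perm <- chi_square_independence(m[2:1, 2:1])
  expect_equal(perm$statistic, res$statistic, tolerance = 1e-12)

  expect_error(chi_square_independence(rbind(c(0, 0), c(5, 5), c(3, 2))),
               "margin")
})

test_that("trend test matches the direct formula, a permutation reference,
           and prop.trend.test", {
  counts <- cbind(non_case = c(9, 5, 1), case = c(1, 5, 9))
  res <- cochran_armitage_trend(counts)

  # direct formula evaluation, independently
  s <- 1:3; n_i <- rowSums(counts); n1 <- counts[, 2]
  pbar <- sum(n1) / sum(n_i)
  Tm <- sum(s * (n1 - n_i * pbar))
  Vm <- pbar * (1 - pbar) * (sum(n_i * s^2) - sum(n_i * s)^2 / sum(n_i))
  expect_equal(res$Z, Tm / sqrt(Vm), tolerance = 1e-12)
  expect_lt(res$p, 0.01)

  # cross-check against the stock chi-square trend test (Z^2 = X2)
  pt <- suppressWarnings(prop.trend.test(n1, n_i, score = s))
  expect_equal(res$Z^2, unname(pt$statistic), tolerance = 1e-10)

  # permutation reference: permuting case labels across levels
  set.seed(61)
  y <- rep(rep(1:0, 3), times = as.vector(t(counts[, c(2, 1)])))
  lev <- rep(1:3, times = n_i)
  obs <- res$Z
  perm_z <- replicate(2000, {
    yp <- sample(y)
    cp <- cbind(tapply(1 - yp, lev, sum), tapply(yp, lev, sum))
    cochran_armitage_trend(cp)$Z
  })
  p_perm <- mean(abs(perm_z) >= abs(obs))
  expect_lt(p_perm, 0.01)
})

test_that("trend Z is antisymmetric in level order and affine-invariant in
           scores", {
  counts <- cbind(c(10, 8, 6, 2), c(2, 4, 6, 10))
  a <- cochran_armitage_trend(counts)
  b <- cochran_armitage_trend(counts[4:1, ])
  expect_equal(b$Z, -a$Z, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
  c_ <- cochran_armitage_trend(counts, scores = 10 + 5 * (1:4))
  expect_equal(c_$Z, a$Z, tolerance = 1e-10)

  expect_error(cochran_armitage_trend(cbind(c(5, 5, 5), c(0, 0, 0))),
               "no variation")
  expect_error(cochran_armitage_trend(cbind(c(5, 5), c(1, 1))), "3 ordered")
})

test_that("flat case proportions give Z = 0, p = 1", {
  res <- cochran_armitage_trend(cbind(c(7, 7, 7), c(3, 3, 3)))
  expect_equal(res$Z, 0)
  expect_equal(res$p, 1)
})

test_that("VIFs are 1 for orthogonal columns, infinite for duplicates, and
           match a planted R^2", {
  X <- cbind(a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4))
  v <- variance_inflation_factors(X)
  expect_equal(v$vif, c(1, 1), tolerance = 1e-10)
  expect_false(any(v$flag))

  X2 <- cbind(x1 = rnorm(30), x2 = 0)
  X2[, 2] <- X2[, 1]
  v2 <- variance_inflation_factors(X2)
  expect_true(all(is.infinite(v2$vif)))
  expect_true(all(v2$flag))

  # x2 = x1 + noise with var(noise) = var(x1)/9 => R^2 = 0.9, VIF = 10
  set.seed(71)
  n <- 20000
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, sd = 1 / 3)
  v3 <- variance_inflation_factors(cbind(x1, x2))
  expect_equal(v3$vif[2], 10, tolerance = 0.5)

  # independent cross-check against car::vif on a fitted model
  y <- rnorm(n)
  cv <- car::vif(lm(y ~ x1 + x2))
  expect_equal(v3$vif, unname(cv), tolerance = 1e-6)
})

test_that("VIF is always at least 1", {
  set.seed(73)
  X <- matrix(rnorm(200), 50, 4)
  v <- variance_inflation_factors(X)
  expect_true(all(v$vif >= 1 - 1e-10))
  expect_error(variance_inflation_factors(cbind(a = rep(1, 5), b = rep(2, 5))),
               "non-constant")
})
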