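test_that("tie-free Spearman matches the rank-difference formula exactly", {
  s <- spearmanCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(s$r, 0.8)                       # 1 - 6*2 / (4*15)
  expect_equal(s$method, "eq_rankdiff")

  set.seed(401)
  x <- rnorm(11)
  expect_equal(spearmanCorrelation(x, x)$r, 1)
  expect_equal(spearmanCorrelation(x, -x)$r, -1)
  expect_equal(spearmanCorrelation(x, x)$p_value, 0)   # documented convention

  # rank-difference formula and rank-Pearson agree to 1e-12 when tie-free
  for (i in 1:30) {
    x <- rnorm(15); y <- rnorm(15)
    rEq <- spearmanCorrelation(x, y)$r
    rRp <- cor(rank(x), rank(y))
    expect_equal(rEq, rRp, tolerance = 1e-12)
  }
})

test_that("Spearman r and t-approximation p match the standard reference", {
  set.seed(402)
  for (i in 1:20) {
    x <- rnorm(25); y <- 0.5 * x + rnorm(25)
    s <- spearmanCorrelation(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE, continuity = FALSE))
    expect_equal(s$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(s$p_value, ref$p.value, tolerance = 1e-10)
  }
  # exact small-sample option agrees with the exact reference distribution
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.9, 0.5)
  expect_equal(spearmanCorrelation(x, y, pMethod = "exact")$p_value,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
})

test_that("ties switch to average-rank Pearson", {
  x <- c(1, 2, 2, 3, 5)
  y <- c(2, 1, 4, 4, 6)
  s <- spearmanCorrelation(x, y)
  expect_equal(s$method, "rank_pearson")
  expect_equal(s$r, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("Spearman is symmetric and invariant under monotone transforms", {
  set.seed(403)
  transforms <- list(function(v) exp(v), function(v) v^3,
                     function(v) atan(v), function(v) 2 * v + 7)
  for (i in 1:25) {
    x <- rnorm(12); y <- rnorm(12)
    r0 <- spearmanCorrelation(x, y)$r
    expect_equal(spearmanCorrelation(y, x)$r, r0, tolerance = 1e-12)
    f <- transforms[[sample(length(transforms), 1)]]
    expect_equal(spearmanCorrelation(f(x), y)$r, r0, tolerance = 1e-12)
    expect_equal(spearmanCorrelation(x, f(y))$r, r0, tolerance = 1e-12)
  }
})

test_that("Spearman input contracts are enforced", {
  expect_error(spearmanCorrelation(1:3, 1:4), "equal length")
  expect_error(spearmanCorrelation(1, 2), "at least 2")
  expect_error(spearmanCorrelation(c(1, NA, 3), c(1, 2, 3)), "missing")
})

test_that("the t-approximated p-value is calibrated under the null", {
  set.seed(404)
  hits <- 0L
  for (i in 1:4000) {
    if (spearmanCorrelation(rnorm(20), rnorm(20))$p_value < 0.05)
      hits <- hits + 1L
  }
  expect_gt(hits / 4000, 0.035)
  expect_lt(hits / 4000, 0.065)
})

test_that("linear calibration recovers exact and noisy relationships", {
  x <- 1:10
  fit <- linearCalibration(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  set.seed(405)
  # pure noise around a constant: R^2 near zero
  expect_lt(linearCalibration(rnorm(200), rnorm(200))$r_squared, 0.2)

  # population R^2 = var(x) / (var(x) + sigma^2) = 0.9
  x <- rnorm(500)
  sigma <- sqrt(var(x) * (1 / 0.9 - 1))
  fit9 <- linearCalibration(x, x + rnorm(500, 0, sigma))
  expect_lt(abs(fit9$r_squared - 0.9), 0.05)

  expect_error(linearCalibration(rep(3, 5), 1:5), "constant")
})

test_that("two-group comparison: exact small-sample and limiting behaviour", {
  # complete separation at n = 2 + 2: exact two-sided p = 2/6
  expect_equal(compareGroups(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  # identical groups: maximal overlap
  expect_equal(compareGroups(c(1, 2, 3), c(1, 2, 3)), 1)
  # symmetry
  a <- c(5, 9, 2, 7); b <- c(1, 3, 8)
  expect_equal(compareGroups(a, b), compareGroups(b, a))
  # strongly separated large samples
  set.seed(406)
  expect_lt(compareGroups(rnorm(50), rnorm(50, 10)), 1e-6)
  # Welch alternative matches the standard implementation
  expect_equal(compareGroups(a, b, test = "welch"),
               t.test(a, b, var.equal = FALSE)$p.value)
  expect_error(compareGroups(numeric(0), 1:3), "non-empty")
})
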