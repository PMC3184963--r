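test_that("GSI closed forms and bounds", {
  expect_equal(gsi(grade_distribution(c(100, 0, 0, 0, 0))), 0)
  expect_equal(gsi(grade_distribution(c(0, 0, 0, 0, 100))), 4)
  expect_equal(gsi(grade_distribution(c(20, 20, 20, 20, 20))), 2.0)
  expect_equal(gsi(grade_distribution(c(0, 0, 100, 0, 0))), 2.0)
  expect_error(grade_distribution(c(50, 0, 0, 0, 0)), "sum to 100")
  expect_error(grade_distribution(c(110, -10, 0, 0, 0)), "non-negative")
  expect_error(grade_distribution(c(20, 20, 20, 20)), "5 entries")
})

test_that("GSI is linear under distribution mixtures", {
  set.seed(1)
  for (i in 1:20) {
    F <- runif(5); F <- 100 * F / sum(F)
    G <- runif(5); G <- 100 * G / sum(G)
    a <- runif(1)
    mix <- grade_distribution(a * F + (1 - a) * G)
    expect_equal(gsi(mix),
                 a * gsi(grade_distribution(F)) + (1 - a) * gsi(grade_distribution(G)),
                 tolerance = 1e-12)
  }
})

test_that("grades tabulate into exact percentage distributions", {
  d <- grades_to_distribution(rep(0L, 80))
  expect_equal(d$F, c(100, 0, 0, 0, 0))
  expect_equal(d$n_glomeruli, 80)
  d2 <- grades_to_distribution(c(0, 4))
  expect_equal(d2$F, c(50, 0, 0, 0, 50))
  expect_equal(gsi(d2), 2.0)
  set.seed(2)
  g <- sample(0:4, 80, replace = TRUE)
  expect_equal(sum(grades_to_distribution(g)$F), 100)
  expect_error(grades_to_distribution(c(0, 5)), "positions")
})

test_that("geometric mean and tolerance factor match hand calculation", {
  s <- geometric_summary(c(10, 10, 10))
  expect_equal(s$geometric_mean, 10)
  expect_equal(s$tolerance_factor, 1.0)
  # {1, 100}: logs {0, ln 100}, mean 2.3026, SEM 2.3026, both exp = 10
  s2 <- geometric_summary(c(1, 100))
  expect_equal(s2$geometric_mean, 10)
  expect_equal(s2$tolerance_factor, 10)
  # scale equivariance
  x <- c(3, 7, 11, 19)
  a <- geometric_summary(x); b <- geometric_summary(5 * x)
  expect_equal(b$geometric_mean, 5 * a$geometric_mean)
  expect_equal(b$tolerance_factor, a$tolerance_factor)
  expect_error(geometric_summary(c(1, -2)), "positive")
  expect_error(geometric_summary(5), "at least 2")
})

test_that("group comparison: identity, symmetry, and the skewed mode", {
  a <- c(1.2, 1.4, 1.1, 1.3)
  same <- compare_groups(a, a)
  expect_equal(same$p_value, 1.0, tolerance = 1e-12)
  expect_equal(same$mean_difference, 0)
  b <- a * 1.8
  ab <- compare_groups(a, b); ba <- compare_groups(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$mean_difference, -ba$mean_difference)
  # skewed mode on lognormal data equals normal mode on its logs
  set.seed(3)
  x <- exp(rnorm(8, 1, 0.6)); y <- exp(rnorm(8, 1.8, 0.6))
  sk <- compare_groups(x, y, skewed = TRUE)
  lg <- compare_groups(log(x), log(y))
  expect_equal(sk$p_value, lg$p_value, tolerance = 1e-12)
  expect_equal(sk$group_a$geometric_mean, exp(mean(log(x))))
  expect_error(compare_groups(c(-1, 2, 3), y, skewed = TRUE), "positive")
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})
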