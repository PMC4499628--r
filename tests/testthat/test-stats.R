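test_that("relative difference matches hand arithmetic and its symmetries", {
  expect_equal(relative_difference(0.88, 0.98), 0.10 * 100 / 0.93)
  expect_equal(relative_difference(1.0, 3.0), 100)
  expect_identical(relative_difference(1.7, 1.7), 0)
  expect_error(relative_difference(1, -1), class = "ava_input_error")

  set.seed(2)
  a <- runif(50, 0.1, 3); b <- runif(50, 0.1, 3); k <- runif(50, 0.1, 10)
  expect_equal(relative_difference(a, b), relative_difference(b, a))
  expect_equal(relative_difference(k * a, k * b), relative_difference(a, b))
})

test_that("Bland-Altman handles degenerate and constant differences", {
  x <- c(1, 2, 3, 4)
  same <- bland_altman(x, x)
  expect_identical(same$mean_diff, 0)
  expect_identical(c(same$loa_low, same$loa_high), c(0, 0))
  expect_identical(same$bias_p, 1)

  shifted <- bland_altman(x + 0.25, x)
  expect_identical(shifted$mean_diff, 0.25)
  expect_identical(c(shifted$loa_low, shifted$loa_high), c(0.25, 0.25))
  expect_identical(shifted$bias_p, 0)

  expect_error(bland_altman(1:3, 1:4), class = "ava_input_error")
  expect_error(bland_altman(1:2, 2:3), class = "ava_input_error")
})

test_that("Bland-Altman agrees with a direct computation and the t test", {
  set.seed(31)
  x <- rnorm(25, 1.0, 0.3); y <- x + rnorm(25, -0.1, 0.18)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  tt <- t.test(d)
  expect_equal(ba$bias_p, tt$p.value)
  expect_equal(c(ba$ci_low, ba$ci_high), as.numeric(tt$conf.int))
  # the CI of the mean is strictly inside the limits of agreement
  expect_gt(ba$ci_low, ba$loa_low)
  expect_lt(ba$ci_high, ba$loa_high)
})

test_that("observer variability reproduces hand-computed pairs", {
  v <- observer_variability(c(1.0, 2.0), c(1.1, 1.8))
  expect_equal(v$per_pair_relative_diff,
               c(0.1 * 100 / 1.05, 0.2 * 100 / 1.9))
  expect_equal(v$mean_rd, mean(c(100 / 10.5, 200 / 19)))
  same <- observer_variability(c(0.8, 0.9, 1.0), c(0.8, 0.9, 1.0))
  expect_identical(same$mean_rd, 0)
  expect_identical(same$sd_rd, 0)
  expect_warning(z <- observer_variability(c(1, 0.5), c(-1, 0.4)), "zero mean")
  expect_equal(z$n, 1L)
})

test_that("repeat measurements with 5% multiplicative noise land near the expected variability", {
  # each measurement carries CV 5% noise, so the difference has SD
  # ~ 5%*sqrt(2) and E|rd| ~ 5.64%
  set.seed(77)
  means <- replicate(20, {
    truth <- runif(25, 0.5, 1.5)
    m1 <- truth * (1 + rnorm(25, 0, 0.05))
    m2 <- truth * (1 + rnorm(25, 0, 0.05))
    observer_variability(m1, m2)$mean_rd
  })
  expect_gt(mean(means), 4)
  expect_lt(mean(means), 8)
})
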