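test_that("soft-Heaviside has logistic values, symmetry and saturation", {
  expect_equal(soft_heaviside(0), 0.5)
  expect_equal(soft_heaviside(2), 1 / (1 + exp(-2)))
  expect_equal(soft_heaviside(1e6), 1)
  expect_equal(soft_heaviside(-1e6), 0)
  set.seed(1)
  x <- runif(1e6, -30, 30)
  h <- soft_heaviside(x)
  expect_true(all(h > 0 & h < 1))
  expect_equal(h + soft_heaviside(-x), rep(1, length(x)), tolerance = 1e-12)
  xs <- sort(runif(1000, -30, 30))
  expect_true(all(diff(soft_heaviside(xs)) >= 0))
})

test_that("number/concentration conversion follows N = 0.6 V [S]", {
  expect_equal(number_to_concentration(9, 1), 15)
  expect_equal(number_to_concentration(0, 7), 0)
  expect_equal(concentration_to_number(15, 10), 90)
  expect_error(number_to_concentration(5, 0), "positive")
  expect_error(concentration_to_number(5, -1), "positive")
})

test_that("division fraction reproduces the published medium-specific ratios", {
  expect_equal(division_fraction(100), 0.42, tolerance = 0.005)
  expect_equal(division_fraction(150), 0.39, tolerance = 0.005)
  f <- division_fraction(100)
  expect_equal(f + (1 - f), 1)
  expect_error(division_fraction(0), "positive")
})

test_that("division-fraction sampling matches its truncated normal law", {
  set.seed(7)
  f <- sample_division_fraction(1e5)
  expect_equal(mean(f), 0.42, tolerance = 0.002)
  expect_equal(sd(f), 0.05, tolerance = 0.003)
  expect_true(all(f > 0.05 & f < 0.95))
  expect_equal(sample_division_fraction(3, sd = 0), rep(division_fraction(100), 3))
})

test_that("zero-noise Langevin step is exactly the deterministic Euler step", {
  x <- 120; a <- 4; b <- 0.05; dt <- 0.01
  expect_identical(langevin_step_class1(x, a, b, dt, zeta1 = 0, zeta2 = 0,
                                        mbar = 5),
                   x + (a - b * x) * dt)
  expect_error(langevin_step_class1(1, -1, 0.1, 0.01), ">= 0")
})

test_that("growth law doubles volume over one mass-doubling time", {
  g <- growth_law(v0 = 10, mdt = 100)
  expect_equal(g$mu, log(2) / 100)
  tr <- simulate_start(v0 = 10, tend = 100, record_dt = 100,
                       params = start_params(mu = log(2) / 100))
  expect_equal(tr$v[nrow(tr)] / tr$v[1], 2, tolerance = 1e-3)
  expect_error(growth_law(v0 = -1, mu = 0.007), "positive")
})
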