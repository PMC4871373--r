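test_that("exact SSA of a birth-death process is stationary Poisson", {
  net <- reaction_network("x", list(
    list(rate = 10, reactants = c(), change = c(x = 1)),
    list(rate = 1, reactants = c(x = 1), change = c(x = -1))))
  tr <- ssa_simulate(net, c(x = 10), tend = 1.2e4, record_dt = 1, seed = 99)
  x <- tr$x[tr$t > 200]
  expect_equal(mean(x), 10, tolerance = 0.05)
  # chi-squared goodness of fit against Poisson(10)
  ks <- 0:25
  obs <- tabulate(pmin(x, 25) + 1, 26)
  p <- stats::dpois(ks, 10); p[26] <- 1 - stats::ppois(24, 10)
  keep <- length(x) * p > 5
  chi2 <- sum((obs[keep] - length(x) * p[keep])^2 / (length(x) * p[keep]))
  # samples are autocorrelated (tau = 1/B); scale dof conservatively
  expect_lt(chi2, stats::qchisq(0.99, sum(keep) - 1) * 3)
  expect_error(
    ssa_simulate(reaction_network("x", list(
      list(rate = 1, reactants = c(x = 1), change = c(x = -1)))),
      c(x = -5), 1), "negative propensity")
})

test_that("protein-only CLE reproduces the 1/<N> stationary noise law", {
  a <- 50; b <- 0.5
  s <- bd_cle_samples(a, b, mbar = NULL, dt = 0.01, n_steps = 1e6,
                      burn = 1e5, thin = 25, seed = 11)
  cv2 <- stats::var(s) / mean(s)^2
  expect_equal(cv2, b / a, tolerance = 0.1)
})

test_that("lumped mRNA term reproduces two-stage birth-death noise within 10%", {
  # rates in the regime of the yeast model species: mRNA half-life ~1 min
  # (k_dm = 0.7), protein half-life ~7 min (k_dp = 0.1, ClbS-like)
  kdm <- 0.7; kdp <- 0.1
  for (m in c(2, 5, 20)) {
    ksm <- m * kdm
    ksp <- 50 * kdp            # <N> = m * ksp/kdp = 50 m
    N <- m * ksp / kdp
    ssa <- bd2_ssa_samples(ksm, kdm, ksp, kdp, tend = 5e4, sample_dt = 5,
                           burn_t = 500, seed = m)
    cle <- bd_cle_samples(a = N * kdp, b = kdp, mbar = m, kdm = kdm,
                          dt = 0.01, n_steps = 2e6, burn = 2e5, thin = 25,
                          seed = m + 50)
    cv2_ssa <- stats::var(ssa) / mean(ssa)^2
    cv2_cle <- stats::var(cle) / mean(cle)^2
    cv2_theory <- 1 / N + (1 / m) * kdp / (kdp + kdm)
    expect_equal(cv2_cle, cv2_theory, tolerance = 0.12,
                 label = paste("CLE cv2 at m =", m))
    expect_equal(cv2_cle, cv2_ssa, tolerance = 0.15,
                 label = paste("CLE vs SSA cv2 at m =", m))
  }
})

test_that("removing mRNA-inherited noise strictly reduces the stationary CV", {
  for (m in c(2, 5, 20)) {
    with_m <- bd_cle_samples(50, 0.5, mbar = m, dt = 0.01, n_steps = 5e5,
                             burn = 5e4, thin = 25, seed = m)
    without <- bd_cle_samples(50, 0.5, mbar = NULL, dt = 0.01, n_steps = 5e5,
                              burn = 5e4, thin = 25, seed = m)
    expect_gt(sd(with_m) / mean(with_m), sd(without) / mean(without))
  }
})

test_that("identical seeds give bit-identical stochastic trajectories", {
  a <- simulate_start(tend = 30, stochastic = TRUE, seed = 123)
  b <- simulate_start(tend = 30, stochastic = TRUE, seed = 123)
  expect_identical(a, b)
  c <- simulate_start(tend = 30, stochastic = TRUE, seed = 124)
  expect_false(identical(a$cln3, c$cln3))

  p1 <- simulate_pedigree(n_gen = 3, n_founders = 1, seed = 5, burn_in = 0)
  p2 <- simulate_pedigree(n_gen = 3, n_founders = 1, seed = 5, burn_in = 0)
  expect_identical(p1, p2)
})

test_that("stochastic Start model variants alter noise as designed", {
  # ClbS in a post-Start cell is dominated by mRNA-inherited noise (its mRNA
  # count ~25-45); the protein-only variant fluctuates much less
  get_cv <- function(mode, seed) {
    tr <- simulate_start(tend = 150, stochastic = TRUE, mode = mode,
                         seed = seed, fixed_v = TRUE, v0 = 35)
    x <- tr$clbs[tr$t > 60]
    sd(x) / mean(x)
  }
  cv_mrna <- mean(vapply(1:3, function(s) get_cv("mrna", s), numeric(1)))
  cv_prot <- mean(vapply(1:3, function(s) get_cv("protein-only", s),
                         numeric(1)))
  expect_gt(cv_mrna, cv_prot)
  tr <- simulate_start(tend = 5, stochastic = TRUE, mode = "explicit-mrna",
                       seed = 1)
  expect_true(all(c("m_n3", "m_bs", "m_i5", "m_hi5") %in% names(tr)))
})

test_that("division gate adds hysteresis and degenerates to the plain rule", {
  p <- cellcycle_params()
  flags <- list(b_udna = 0, b_spc = 0, b_oriflag = 0, armed = 0)
  mk <- function(clb2) c(bud = 0, ori = 0, spn = 0, clb2 = clb2, clb5 = 0)
  # jitter around K_EZ without reaching K_flag: no division while disarmed
  r1 <- apply_event_rules(mk(0.45), mk(0.35), flags, p, gate = TRUE)
  expect_false("division" %in% r1$events)
  # arm by exceeding K_flag, then a downcrossing fires exactly once
  r2 <- apply_event_rules(mk(0.45), mk(0.9), r1$flags, p, gate = TRUE)
  expect_equal(r2$flags$armed, 1)
  r3 <- apply_event_rules(mk(0.9), mk(0.35), r2$flags, p, gate = TRUE)
  expect_true("division" %in% r3$events)
  expect_equal(r3$flags$armed, 0)
  r4 <- apply_event_rules(mk(0.45), mk(0.35), r3$flags, p, gate = TRUE)
  expect_false("division" %in% r4$events)
  # K_flag = K_EZ reduces the gate to the plain downcrossing rule
  p2 <- cellcycle_params(k_flag = p[["k_ez"]])
  r5 <- apply_event_rules(mk(0.45), mk(0.35), flags, p2, gate = TRUE)
  expect_true("division" %in% r5$events)
})
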