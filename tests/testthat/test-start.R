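test_that("newborn initial state sits at the constitutive steady levels", {
  x0 <- start_init(v0 = 10)
  expect_equal(unname(x0[c("hi5", "sbf_t", "whi5_t")]),
               c(1275, 1530, 5363), tolerance = 1e-3)
  expect_equal(unname(x0["whi5_a"]), unname(x0["whi5_t"])) # all Whi5 active
  expect_equal(unname(x0[c("cln3", "clbs")]), c(0, 0))
  # free SBF at t = 0 is zero: active Whi5 exceeds total SBF
  tr <- simulate_start(tend = 0.1, record_dt = 0.1)
  expect_equal(tr$sbf[1], 0)
})

test_that("Cln3 relaxes to its analytic steady state at fixed volume", {
  p <- start_params()
  v <- 10
  ss <- p[["ks_n3"]] * v^2 * (p[["ks_mn3"]] / p[["kd_mn3"]]) / p[["kd_n3"]]
  tr <- simulate_start(v0 = v, tend = 80, fixed_v = TRUE)
  expect_equal(tr$cln3[nrow(tr)], ss, tolerance = 1e-3)
})

test_that("deterministic Start and G1/S transitions occur at the known times", {
  tr <- simulate_start(v0 = 10, tend = 300)
  tt <- start_transition_times(tr)
  expect_equal(tt$t1, 145, tolerance = 2 / 145)
  expect_equal(tt$t_g1, 153, tolerance = 2 / 153)
})

test_that("crossing detection interpolates and handles edge cases", {
  # constant trajectory below threshold
  flat <- tibble::tibble(t = 0:10, v = 1, y = 1)
  expect_true(is.na(detect_first_crossing(flat, "y", 100, v_aware = FALSE)))
  expect_error(detect_first_crossing(flat[0, ], "y", 1), "empty")
  # synthetic linear ramp: concentration y/(0.6v) crosses thr at t = 6 exactly
  ramp <- tibble::tibble(t = seq(0, 10, 0.5), v = 1,
                         y = 0.6 * 2 * seq(0, 10, 0.5))
  expect_equal(detect_first_crossing(ramp, "y", 12), 6, tolerance = 1e-10)
})

test_that("transition times decrease with birth size; T2 is nearly constant", {
  # grid spans newborn sizes below the Start-threshold volume (~30 fL)
  tab <- timing_vs_birth_size(c(10, 15, 20, 25, 30), "scm")
  expect_true(all(diff(tab$t1) <= 0))
  expect_true(all(diff(tab$t_g1) <= 0))
  expect_lt(tab$t1[tab$v0 == 30], tab$t1[tab$v0 == 10])
  expect_lt(diff(range(tab$t2)), 0.2 * mean(tab$t2))
  expect_error(timing_vs_birth_size(c(-1, 10)), "positive")
})

test_that("constitutive protein concentrations stay constant as the cell grows", {
  # under balanced exponential growth the steady level is k_s m V/(k_d + mu);
  # starting there, the concentration of every constitutively expressed
  # protein stays constant (to < 5%) as the cell doubles its volume
  p <- start_params()
  v0 <- 10
  bal <- c(
    hi5 = p[["ks_hi5"]] * v0 * (p[["ks_mhi5"]] / p[["kd_mhi5"]]) /
      (p[["kd_hi5"]] + p[["mu"]]),
    whi5_t = p[["ks_i5"]] * v0 * (p[["ks_mi5"]] / p[["kd_mi5"]]) /
      (p[["kd_i5"]] + p[["mu"]]),
    sbf_t = p[["ks_bf"]] * v0 / (p[["kd_bf"]] + p[["mu"]]))
  bal["whi5_a"] <- bal[["whi5_t"]]
  tr <- simulate_start(v0 = v0, tend = log(2) / p[["mu"]], init = bal)
  expect_equal(tr$v[nrow(tr)] / v0, 2, tolerance = 1e-3)
  for (sp in c("hi5", "whi5_t", "sbf_t")) {
    conc <- number_to_concentration(tr[[sp]], tr$v)
    expect_lt(max(abs(conc - conc[1]) / conc[1]), 0.05)
  }
})

test_that("active Whi5 never exceeds total Whi5", {
  tr <- simulate_start(tend = 300)
  expect_true(all(tr$whi5_a <= tr$whi5_t + 1e-9))
  trs <- simulate_start(tend = 200, stochastic = TRUE, seed = 4)
  expect_true(all(trs$whi5_a <= trs$whi5_t + 1e-9))
})

test_that("halving the step size changes deterministic event times by < 1%", {
  t1 <- start_transition_times(simulate_start(tend = 300, dt = 0.01))
  t2 <- start_transition_times(simulate_start(tend = 300, dt = 0.005))
  expect_lt(abs(t1$t1 - t2$t1) / t2$t1, 0.01)
  expect_lt(abs(t1$t_g1 - t2$t_g1) / t2$t_g1, 0.01)
})

test_that("building the model validates its parameter set", {
  expect_error(build_start_scm(start_params()[-1]), "missing")
  expect_error(start_params(bogus_key = 1), "unknown")
})
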