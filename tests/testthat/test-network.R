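test_that("influence sums weighted regulators with structural signs", {
  sp <- class2_spec("y", total = 1, gamma = 1, sigma = 1, w0 = 1)
  expect_equal(influence(sp, c(a = 5)), 1)

  # the Whi5 influence of the full model at a resting state: only the
  # background dephosphorylation term survives
  p <- cellcycle_params()
  sp2 <- class2_spec("whi5_a", total = p[["whi5_t"]], gamma = 1, sigma = 1,
                     w0 = p[["om_dp_whi5"]],
                     pos = c(cdc14 = p[["om_dp_whi5_14"]]),
                     neg = c(cln3 = p[["om_p_whi5_n3"]],
                             bck2 = p[["om_p_whi5_k2"]],
                             cln2 = p[["om_p_whi5_n2"]],
                             clb5 = p[["om_p_whi5_b5"]]))
  rest <- c(cdc14 = 0, cln3 = 0, bck2 = 0, cln2 = 0, clb5 = 0)
  expect_equal(influence(sp2, rest), 1)

  # random weights and state match a term-by-term summation oracle
  set.seed(42)
  for (i in 1:20) {
    pos <- setNames(runif(3), c("a", "b", "c"))
    neg <- setNames(runif(2), c("d", "e"))
    st <- setNames(runif(5, 0, 10), c("a", "b", "c", "d", "e"))
    sp3 <- class2_spec("y", 1, 1, 1, w0 = -0.3, pos = pos, neg = neg)
    oracle <- -0.3 + sum(vapply(names(pos), function(n) pos[[n]] * st[[n]],
                                numeric(1))) -
      sum(vapply(names(neg), function(n) neg[[n]] * st[[n]], numeric(1)))
    expect_equal(influence(sp3, st), oracle)
  }
  expect_error(influence(sp2, c(cdc14 = 0)), "unknown regulator")
  expect_error(class2_spec("y", 1, 1, 1, pos = c(a = -1)), "non-negative")
})

test_that("class-3 binding rules conserve totals and respect non-negativity", {
  single <- class3_spec("y", "single", c("yt", "it"))
  expect_equal(unname(class3_free(single, c(yt = 5, it = 7))), 0)
  expect_equal(unname(class3_free(single, c(yt = 7, it = 5))), 2)

  shared <- class3_spec(c("y1", "y2"), "shared", c("y1t", "y2t", "it"))
  v <- class3_free(shared, c(y1t = 10, y2t = 10, it = 10))
  expect_equal(unname(v[1:2]), c(5, 5))

  # degenerate denominator convention
  v0 <- class3_free(shared, c(y1t = 0, y2t = 0, it = 4))
  expect_equal(unname(v0), c(0, 0, 4))

  # brute-force conservation oracle on random non-negative triples
  set.seed(3)
  for (i in 1:50) {
    s <- c(y1t = runif(1, 0, 20), y2t = runif(1, 0, 20), it = runif(1, 0, 30))
    v <- class3_free(shared, s)
    expect_true(all(v >= 0))
    bound_partner <- (s[["y1t"]] - v[[1]]) + (s[["y2t"]] - v[[2]])
    bound_inhibitor <- s[["it"]] - v[[3]]
    expect_equal(bound_partner, bound_inhibitor, tolerance = 1e-12)
    expect_equal(v[[1]] + v[[2]],
                 max(0, s[["y1t"]] + s[["y2t"]] - s[["it"]]),
                 tolerance = 1e-12)
  }

  pri <- class3_spec(c("y1", "y2"), "priority", c("y1t", "y2t", "it"))
  vp <- class3_free(pri, c(y1t = 4, y2t = 6, it = 5))
  expect_equal(unname(vp[1:2]), c(0, 5)) # inhibitor saturates partner 1 first

  mn <- class3_spec("c", "min", c("a", "b"))
  expect_equal(unname(class3_free(mn, c(a = 2, b = 7))), 2)
})

test_that("generic Euler stepper finds fixed points and rejects bad input", {
  net0 <- toy_class1_net(a = 0, b = 0)
  st <- scm_initial_state(net0, c(x = 3))
  stepped <- euler_step(net0, st, v = 1, dt = 0.01)
  expect_equal(stepped$state[["x"]], 3)
  expect_error(euler_step(net0, st, v = 1, dt = 0), "positive")

  net <- toy_class1_net(a = 2, b = 0.1)
  tr <- scm_simulate(net, tend = 120, dt = 0.01, record_dt = 20)
  expect_equal(tr$x[nrow(tr)], 20, tolerance = 0.01) # A/B within 1%
})

test_that("a stiff class-2 variable behaves like a Boolean switch", {
  # with gamma and sigma large, the activity sits within 0.01 of {0, 1}
  # for > 95% of a relaxation through an input sign flip
  net <- toy_class2_net(gamma = 100, sigma = 100, w0 = 0.2)
  tr1 <- scm_simulate(net, init = c(y = 0), tend = 10, dt = 0.001,
                      record_dt = 0.01)
  net2 <- toy_class2_net(gamma = 100, sigma = 100, w0 = -0.2)
  tr2 <- scm_simulate(net2, init = c(y = 1), tend = 10, dt = 0.001,
                      record_dt = 0.01)
  y <- c(tr1$y, tr2$y)
  frac_boolean <- mean(pmin(y, 1 - y) < 0.01)
  expect_gt(frac_boolean, 0.95)
  expect_true(all(y >= 0 & y <= 1))
})

test_that("generic integrator reproduces the compiled Start engine", {
  net <- build_start_scm()
  g <- scm_simulate(net, tend = 20, dt = 0.01, record_dt = 10)
  c <- simulate_start(tend = 20, dt = 0.01, record_dt = 10)
  for (nm in c("v", "cln3", "clbs", "whi5_a", "whi5_t", "hi5", "sbf_t", "sbf"))
    expect_equal(g[[nm]], c[[nm]], tolerance = 1e-10, label = nm)
})

test_that("generic integrator reproduces the compiled full-model engine", {
  net <- build_cellcycle_scm()
  g <- scm_simulate(net, tend = 3, dt = 0.01, record_dt = 1)
  c <- simulate_cellcycle(net, tend = 3, dt = 0.01, record_dt = 1)
  nm <- c("cln3", "bck2", "cln2", "whi5_a", "sbf_a", "bud", "clb5_t",
          "clb2_t", "cki_t", "cki_p", "swi5_t", "ori", "cdh1_a", "apc_p",
          "mad2_a", "spn", "cdc20_t", "pds1_t", "ppx_a", "net1_a", "polo_t",
          "polo_a", "tem1_a", "cdc15_a", "sbf", "clb5", "clb2", "cdc14",
          "mcm1_a")
  for (n in nm)
    expect_equal(g[[n]], c[[n]], tolerance = 1e-9, label = n)
})
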