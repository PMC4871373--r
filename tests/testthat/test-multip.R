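test_that("MultiP starts with unphosphorylated Whi5 and fully complexed SBF", {
  x0 <- multip_init(v0 = 10)
  # every Whi5 molecule unphosphorylated (free W0 or in the unphosphorylated
  # complex), all SBF complexed
  expect_equal(x0[["sbf"]], 0)
  expect_equal(x0[["ga"]], 0)
  expect_true(all(x0[c("w1", "w2", "w3", "w4", "w5", "w6", "c1", "c2")] == 0))
  whi5_total <- x0[["w0"]] + x0[["c0"]]
  expect_equal(whi5_total, unname(start_init(v0 = 10)["whi5_t"]))
  expect_equal(x0[["c0"]], unname(start_init(v0 = 10)["sbf_t"]))
})

test_that("Whi5 pool is conserved apart from synthesis/degradation flux", {
  # with Whi5 synthesis and degradation switched off, the ten Whi5-carrying
  # species exactly conserve their sum while phosphorylation, binding and
  # release shuffle molecules among them
  p <- multip_params(ks_i5 = 0, kd_i5 = 0)
  x0 <- multip_init(multip_params(), v0 = 10)  # finite pool from defaults
  tr <- simulate_multip(p, v0 = 10, tend = 50, record_dt = 5, init = x0)
  tot <- rowSums(tr[, c(paste0("w", 0:6), paste0("c", 0:2))])
  expect_equal(tot, rep(tot[1], length(tot)), tolerance = 1e-8)
})

test_that("SSA mean timing pattern tracks the deterministic model", {
  det <- start_transition_times(simulate_multip(tend = 320))
  t1s <- vapply(1:4, function(s) {
    tr <- simulate_multip_ssa(tend = 320, record_dt = 0.5, seed = s)
    start_transition_times(tr)$t1
  }, numeric(1))
  expect_false(any(is.na(t1s)))
  expect_equal(mean(t1s), det$t1, tolerance = 0.25)
})

test_that("SSA conserves the Whi5 pool between synthesis/degradation events", {
  p <- multip_params(ks_i5 = 0, kd_i5 = 0, kd_bf = 0, ks_bf = 0)
  x0 <- round(multip_init(multip_params(), v0 = 10))
  tr <- simulate_multip_ssa(p, v0 = 10, tend = 30, record_dt = 1, seed = 2,
                            init = x0)
  tot <- rowSums(tr[, c(paste0("w", 0:6), paste0("c", 0:2))])
  expect_true(all(tot == tot[1]))
  sbf_tot <- tr$sbf_free + tr$c0 + tr$c1 + tr$c2 + tr$ga
  expect_true(all(sbf_tot == sbf_tot[1]))
})

test_that("model construction validates the parameter inventory", {
  expect_error(build_multip_model(multip_params()[-1]), "missing")
})
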