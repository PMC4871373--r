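cc_param_vector_test <- function(net) net$params

test_that("mutations are validated, non-destructive and order-independent", {
  wild <- build_cellcycle_scm()
  expect_error(apply_mutation(wild, mutant_spec("x", c(ks_clb5_bff = 0))),
               "unknown parameter")
  m1 <- mutant_spec("a", c(ks_clb5 = 0))
  m2 <- mutant_spec("b", c(kd_clb2_20 = 0))
  n12 <- apply_mutation(apply_mutation(wild, m1), m2)
  n21 <- apply_mutation(apply_mutation(wild, m2), m1)
  expect_identical(cc_param_vector_test(n12), cc_param_vector_test(n21))
  # idempotent
  n11 <- apply_mutation(apply_mutation(wild, m1), m1)
  expect_identical(cc_param_vector_test(n11),
                   cc_param_vector_test(apply_mutation(wild, m1)))
  # wild type untouched
  expect_equal(wild$params[["ks_clb5"]], 0.0006)
  expect_equal(wild$params[["rho_14_net1"]], 1)
})

test_that("gene deletion semantics: clb5 deletion drains total Clb5", {
  net <- apply_mutation(build_cellcycle_scm(),
                        mutant_spec("clb5d", c(ks_clb5 = 0, ks_clb5_bf = 0)))
  tr <- simulate_cellcycle(net, tend = 300, record_dt = 5)
  expect_lt(tr$clb5_t[nrow(tr)], 0.01)
})

test_that("phenotype staging follows the event history", {
  wt <- simulate_lineage(n_divisions = 6)
  expect_equal(classify_phenotype(wt)$call, "viable")
  # synthetic arrested record with no Start
  g1 <- tibble::tibble(gen = 0, role = "daughter", t_birth = 0, v_birth = 1,
                       t_start = NA, t_bud = NA, t_ori = NA, t_spn = NA,
                       t_div = NA, v_div = NA, divided = FALSE, sbf_max = 0.05,
                       theta = NA, v_sample = NA, t1 = NA, t_g1 = NA, t2 = NA,
                       tb = NA, tc = NA)
  expect_equal(classify_phenotype(g1)$call, "G1 arrest")
  g1s <- g1; g1s$sbf_max <- 0.9; g1s$t_start <- 30
  expect_equal(classify_phenotype(g1s)$call, "G1/S arrest")
  tel <- g1s; tel$t_bud <- 40; tel$t_ori <- 45; tel$t_spn <- 80
  expect_equal(classify_phenotype(tel)$call, "telophase arrest")
})

test_that("the bundled catalogue reproduces the documented phenotypes", {
  scr <- screen_mutants()
  expect_true(all(scr$match))
  expect_equal(scr$call[scr$name == "wild type"], "viable")
  expect_equal(scr$call[scr$name == "CLB2-dbΔ clb5Δ"], "telophase arrest")
  expect_equal(scr$call[scr$name == "CLB2-dbΔ clb5Δ GAL-SIC1 (galactose)"],
               "viable")
  expect_identical(nrow(screen_mutants(list())), 0L)
})

test_that("arrest calls are stable under a longer horizon", {
  net <- apply_mutation(build_cellcycle_scm(),
                        mutant_spec("dbd", clb2_db_overrides()))
  r1 <- simulate_lineage(net, n_divisions = 5, horizon = 1000)
  r2 <- simulate_lineage(net, n_divisions = 5, horizon = 2000)
  expect_equal(classify_phenotype(r1)$call, "telophase arrest")
  expect_equal(classify_phenotype(r2)$call, "telophase arrest")
})

test_that("the deterministic screen is reproducible", {
  s1 <- screen_mutants(mutant_catalogue()[1:2])
  s2 <- screen_mutants(mutant_catalogue()[1:2])
  expect_identical(s1, s2)
})
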