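test_that("initial class-3 values follow their defining identities", {
  tr <- simulate_cellcycle(tend = 0.1, record_dt = 0.1)
  r0 <- tr[1, ]
  # free SBF at birth: active Whi5 exceeds unphosphorylated SBF
  expect_equal(r0$sbf, max(0, 0.6560 - 1.7238))
  expect_equal(r0$sbf, 0)
  expect_equal(r0$cdc14, max(0, 2 - 0.1086))
  expect_equal(r0$tem1_cdc15, min(0.8592, 0.9823))
  tot <- r0$clb5_t + r0$clb2_t
  expect_equal(r0$clb5, max(0, r0$clb5_t / tot * (tot - r0$cki_t)))
})

test_that("Cdh1 relaxes to full activity when its inhibitors are removed", {
  net <- build_cellcycle_scm(cellcycle_params(om_i_cdh1_e = 0))
  tr <- simulate_cellcycle(net, tend = 15, record_dt = 1, fixed_v = TRUE)
  # with no inhibitory drive and Cdc14 > 0 the activity saturates at the total
  expect_equal(tr$cdh1_a[nrow(tr)], 1, tolerance = 1e-3)
})

test_that("wild-type daughter lineage settles on the known limit cycle", {
  rec <- simulate_lineage(n_divisions = 10, follow = "daughter",
                          stochastic = FALSE)
  d <- rec[rec$divided, ]
  # periodic orbit: period stable to < 0.5% over the last cycles
  late <- tail(d$tc, 5)
  expect_lt(diff(range(late)) / mean(late), 0.005)
  # daughter T1 = 59 min (deterministic)
  expect_equal(tail(d$t1, 1), 59, tolerance = 3 / 59)
  # order of events within each settled cycle
  s <- tail(d, 5)
  expect_true(all(s$t_start < s$t_bud & s$t_bud < s$t_ori &
                  s$t_ori < s$t_spn & s$t_spn < s$t_div))
  # period identity
  expect_equal(s$t1 + s$t2 + s$tb, s$tc, tolerance = 1e-9)
})

test_that("mother/daughter cycle times average to the mass-doubling time", {
  d <- simulate_lineage(n_divisions = 10, follow = "daughter")
  m <- simulate_lineage(n_divisions = 10, follow = "mother")
  tcs <- c(tail(d$tc[d$divided], 4), tail(m$tc[m$divided], 4))
  expect_equal(mean(tcs), 100, tolerance = 2 / 100)
})

test_that("class-3 identities hold along the trajectory", {
  rec <- simulate_lineage(n_divisions = 3, record_traj = TRUE, record_dt = 0.5)
  tr <- attr(rec, "trajectory")
  expect_true(all(tr$cdc20_apc_p + tr$cdc20_apc <= tr$cdc20_a + 1e-9))
  expect_true(all(tr$cdc20_a <= tr$cdc20_t + 1e-9))
  expect_true(all(tr$cki_p <= tr$cki_t + 1e-9))
  expect_true(all(tr$whi5_a <= 2.5 + 1e-9))
  expect_true(all(as.matrix(tr[, -1]) >= -1e-12))
  # free + bound reconstructs totals for the CKI:Clb complexes
  bound <- (tr$clb5_t - tr$clb5) + (tr$clb2_t - tr$clb2)
  expect_true(all(abs(bound - pmin(tr$cki_t, tr$clb5_t + tr$clb2_t)) < 1e-9))
})

test_that("event rules fire in sequence and reset state at division", {
  p <- cellcycle_params()
  flags <- list(b_udna = 0, b_spc = 0, b_oriflag = 1, armed = 0)
  mk <- function(bud, ori, spn, clb2, clb5 = 0)
    c(bud = bud, ori = ori, spn = spn, clb2 = clb2, clb5 = clb5)
  # Rule 2 consumes the licensing flag and raises the unreplicated-DNA flag
  r <- apply_event_rules(mk(0, 0.9, 0, 1), mk(0, 1.1, 0, 1), flags, p)
  expect_true("ori" %in% r$events)
  expect_equal(r$flags$b_oriflag, 0)
  expect_equal(r$flags$b_udna, 1)
  # a second upcrossing without relicensing does nothing
  r2 <- apply_event_rules(mk(0, 0.9, 0, 1), mk(0, 1.1, 0, 1), r$flags, p)
  expect_false("ori" %in% r2$events)
  # Rule 3 then Rule 4: division resets progress variables and flags
  r3 <- apply_event_rules(mk(0, 1, 0.9, 1), mk(0, 1, 1.1, 1), r2$flags, p)
  expect_equal(r3$flags$b_spc, 1)
  r4 <- apply_event_rules(mk(1.2, 1, 1.2, 0.5), mk(1.2, 1, 1.2, 0.39),
                          r3$flags, p)
  expect_true("division" %in% r4$events)
  expect_equal(unname(r4$cur[c("bud", "spn")]), c(0, 0))
  expect_equal(r4$flags$b_udna, 0)
  expect_equal(r4$flags$b_spc, 0)
  # Rule 5 relicenses origins when total Clb activity is extinguished
  r5 <- apply_event_rules(mk(0, 0.5, 0, 0.3, 0.3), mk(0, 0.5, 0, 0.2, 0.1),
                          r4$flags, p)
  expect_true("relicense" %in% r5$events)
  expect_equal(unname(r5$cur["ori"]), 0)
  expect_equal(r5$flags$b_oriflag, 1)
  # no division when Clb2 never downcrosses K_EZ
  r6 <- apply_event_rules(mk(0, 0, 0, 0.9), mk(0, 0, 0, 0.8), flags, p)
  expect_false("division" %in% r6$events)
})

test_that("asymmetric division conserves volume and resets progress", {
  st <- cellcycle_init()$state
  st["bud"] <- 1.4; st["spn"] <- 1.2
  out <- divide_cell(st, v_n = 2.0, f = 0.42)
  expect_equal(out$daughter$v_n, 0.84)
  expect_equal(out$mother$v_n, 1.16)
  expect_equal(out$daughter$v_n + out$mother$v_n, 2.0)
  expect_equal(unname(out$daughter$state[c("bud", "spn")]), c(0, 0))
  # normalized concentrations inherited unchanged
  expect_equal(out$mother$state[["cln3"]], st[["cln3"]])
  expect_error(divide_cell(st, 2, 1.2), "fraction")
})

test_that("turning off Cdc20-mediated Clb2 degradation blocks division", {
  net <- apply_mutation(build_cellcycle_scm(),
                        mutant_spec("dbd clb5d",
                                    overrides = c(clb2_db_overrides(),
                                                  ks_clb5 = 0,
                                                  ks_clb5_bf = 0)))
  rec <- simulate_lineage(net, n_divisions = 5, horizon = 1000,
                          stochastic = FALSE, record_traj = TRUE,
                          record_dt = 1)
  expect_equal(sum(rec$divided), 0)
  tr <- attr(rec, "trajectory")
  late <- tr[tr$t > 400, ]
  expect_true(all(late$clb2 > cellcycle_params()[["k_ez"]]))
})

test_that("halving dt changes full-model division times by < 1%", {
  r1 <- simulate_lineage(n_divisions = 2, dt = 0.01)
  r2 <- simulate_lineage(n_divisions = 2, dt = 0.005)
  expect_lt(abs(r1$t_div[2] - r2$t_div[2]) / r2$t_div[2], 0.01)
})

test_that("daughter mean birth volume matches the 28 fL volume scale", {
  ped <- simulate_pedigree(n_gen = 8, n_founders = 2, seed = 9)
  d <- ped[ped$role == "daughter" & ped$divided, ]
  expect_gt(nrow(d), 200)
  expect_equal(mean(d$v_birth) * 28, 28, tolerance = 0.08)
})
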