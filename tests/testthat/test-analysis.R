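test_that("bifurcation scan finds two branches only inside the bistable window", {
  b <- bifurcation_scan(v_grid = c(4, 10, 20, 28, 34), relax_t = 2000)
  counts <- table(b$v)
  expect_equal(unname(counts[c("10", "20", "28")]), rep(2L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(counts[c("4", "34")]), rep(1L, 2), ignore_attr = TRUE)
})

test_that("monostable control (no ClbS synthesis) has a single branch", {
  b <- bifurcation_scan(params = start_params(ks_bS = 0),
                        v_grid = c(5, 15, 30), relax_t = 1500)
  expect_equal(nrow(b), 3L)
})

test_that("multi-start relaxation corroborates the two-branch structure", {
  b <- bifurcation_scan(v_grid = c(12, 20), relax_t = 1500, n_starts = 6,
                        seed = 2)
  ms <- attr(b, "multistart")
  for (v in c(12, 20)) {
    ends <- ms$endpoint[ms$v == v]
    br <- sort(b$clbs[b$v == v])
    # each random start lands on one of the two branches (within 1%)
    d_low <- abs(ends - br[1]) <= 0.01 * pmax(br[1], 1)
    d_high <- abs(ends - br[2]) <= 0.01 * br[2]
    expect_true(all(d_low | d_high))
    expect_true(any(d_high))
  }
})

test_that("lineage statistics are zero-variance for deterministic records", {
  rec <- simulate_lineage(n_divisions = 9)
  st <- lineage_stats(rec[rec$gen >= 4, ])
  expect_true(all(st$cv < 1e-4, na.rm = TRUE))
  expect_true(all(st$n > 0))
  expect_error(lineage_stats(rec[0, ]), "at least 2")
})

test_that("size-control fit recovers a perfect sizer and a null control", {
  sizer <- synthetic_records(1500, sizer_slope = -1)
  f <- size_control_fit(sizer, role = "daughter", vbar_m = 28,
                        two_segment = FALSE)
  expect_equal(f$slope_single, -1, tolerance = 0.02)
  noctrl <- synthetic_records(1000, sizer_slope = 0, noise_sd = 0.05)
  f0 <- size_control_fit(noctrl, role = "daughter", vbar_m = 28,
                         two_segment = FALSE)
  expect_lt(abs(f0$slope_single), 0.05)
  expect_error(size_control_fit(sizer[1:50, ], vbar_m = 28), "at least 200")
  td <- tidy(f)
  expect_true(all(c("term", "estimate") %in% names(td)))
})

test_that("asynchronous age sampling follows f(theta) = ln2 * 2^(1 - theta)", {
  expect_equal(d_async_age(0) / d_async_age(1), 2)
  expect_equal(stats::integrate(d_async_age, 0, 1)$value, 1, tolerance = 1e-6)
  set.seed(31)
  th <- r_async_age(1e5)
  expect_true(all(th >= 0 & th <= 1))
  cdf <- function(q) 2 - 2^(1 - q) # integral of the density
  ks <- suppressWarnings(ks.test(th, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("growth curve of an all-viable population doubles at the mdt", {
  # synthetic binary-tree population with fixed 150-min cycles
  gens <- 0:6
  pop <- purrr::map_dfr(gens, function(g) {
    d <- tibble::tibble(gen = g, role = "daughter", t_birth = g * 150,
                        t_div = (g + 1) * 150, divided = TRUE, weight = 1,
                        tc = 150)
    d[rep(1, 2^g), ]
  })
  gs <- growth_and_survival(pop, horizon = 900, t_grid = seq(0, 850, 25))
  expect_equal(gs$ndt, 150, tolerance = 0.02)
  expect_equal(gs$survival$p_greater[1], 1)
})

test_that("fold points are insensitive to grid direction within resolution", {
  b1 <- bifurcation_scan(v_grid = seq(4, 36, by = 4), relax_t = 1500,
                         fold_tol = 0.2)
  b2 <- bifurcation_scan(v_grid = rev(seq(4, 36, by = 4)), relax_t = 1500,
                         fold_tol = 0.2)
  expect_equal(attr(b1, "fold_right"), attr(b2, "fold_right"), tolerance = 0.05)
})

test_that("plot methods return ggplot objects", {
  b <- bifurcation_scan(v_grid = c(10, 20), relax_t = 800)
  expect_s3_class(ggplot2::autoplot(b), "ggplot")
  f <- size_control_fit(synthetic_records(1200), role = "daughter",
                        vbar_m = 28)
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  expect_s3_class(plot_start_trajectory(simulate_start(tend = 5)), "ggplot")
  rec <- simulate_lineage(n_divisions = 1, record_traj = TRUE, record_dt = 5)
  expect_s3_class(plot_cellcycle_trajectory(attr(rec, "trajectory")),
                  "ggplot")
})

test_that("independent lineage batches carry per-lineage labels", {
  cells <- simulate_cells(n_lineages = 2, n_divisions = 7, burn_in = 3,
                          seed = 5)
  expect_setequal(unique(cells$lineage), c(1, 2))
  expect_true(all(cells$gen >= 3 | !cells$divided))
})
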