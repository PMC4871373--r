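#' Saddle-node bifurcation scan of the Start model
#'
#' With growth frozen, cell volume becomes a bifurcation parameter of the
#' Start network. For each volume on the grid the scan relaxes the model to
#' steady state from a low-ClbS (newborn-like) and a high-ClbS (post-Start)
#' initial condition — a forward/backward sweep in miniature — and clusters
#' the endpoints into branches. The two fold (saddle-node) volumes bounding
#' the bistable window are then located by bisection on the disappearance of
#' each branch, to `fold_tol` fL.
#'
#' @param model "scm" or "multip".
#' @param params Parameter vector for the chosen model.
#' @param v_grid Volume grid (fL).
#' @param relax_t Relaxation horizon per point (min).
#' @param dt Euler step (min).
#' @param fold_tol Bisection tolerance for fold location (fL).
#' @param n_starts Extra random initial conditions per volume (0 = none) used
#'   to corroborate the branch count.
#' @param seed Seed for the random starts.
#' @return A `bifurcation_scan` tibble (`v`, `branch`, `clbs`, `stable`) with
#'   attributes `fold_left`, `fold_right`.
#' @export
bifurcation_scan <- function(model = c("scm", "multip"), params = NULL,
                             v_grid = seq(2, 40, by = 1), relax_t = 3000,
                             dt = 0.01, fold_tol = 0.1, n_starts = 0,
                             seed = 1L) {
  model <- match.arg(model)
  if (is.null(params))
    params <- if (model == "scm") start_params() else multip_params()

  final_clbs <- function(v, kind, clbs0 = NULL, whi5_frac = NULL) {
    if (model == "scm") {
      x0 <- start_init(params, v)
      if (kind == "high") { x0[["clbs"]] <- 150 * v; x0[["whi5_a"]] <- 0 }
      if (kind == "random") {
        x0[["clbs"]] <- clbs0
        x0[["whi5_a"]] <- whi5_frac * x0[["whi5_t"]]
      }
      xx <- unname(x0[c("cln3", "clbs", "whi5_a", "whi5_t", "hi5", "sbf_t")])
      st <- start_relax_cpp(params, xx, v, relax_t, dt)
      st[2]
    } else {
      x0 <- multip_init(params, v)
      tot <- x0[["w0"]] + x0[["c0"]]
      if (kind == "high") {
        # post-Start state: Whi5 hyper-phosphorylated, SBF free, gene on
        x0[["clbs"]] <- 150 * v
        x0[["sbf"]] <- x0[["c0"]]
        x0[["w0"]] <- 0; x0[["c0"]] <- 0; x0[["w6"]] <- tot
        x0[["ga"]] <- 1
      }
      if (kind == "random") {
        x0[["clbs"]] <- clbs0
        act <- whi5_frac * tot
        x0[["c0"]] <- min(act, x0[["c0"]])
        x0[["sbf"]] <- (x0[["w0"]] + x0[["c0"]]) - x0[["c0"]]
        x0[["w0"]] <- max(0, act - x0[["c0"]])
        x0[["w6"]] <- tot - act
        x0[["sbf"]] <- tot - x0[["w0"]] - x0[["w6"]] - x0[["c0"]]
        x0[["sbf"]] <- max(0, 1530 / 10 * v - x0[["c0"]])
      }
      tr <- multip_sim_cpp(params, unname(x0), v, relax_t, dt, relax_t, TRUE)
      tr[nrow(tr), 8] # ClbS column (t, v, then state order)
    }
  }

  # two distinct branches exist when the endpoints differ by more than one
  # molecule and the low endpoint is well below the high one
  distinct <- function(lo, hi) (hi - lo) > max(1, 0.05 * hi) && lo < 0.5 * hi
  two_at <- function(v) distinct(final_clbs(v, "low"), final_clbs(v, "high"))

  rows <- purrr::map_dfr(v_grid, function(v) {
    lo <- final_clbs(v, "low"); hi <- final_clbs(v, "high")
    two <- distinct(lo, hi)
    if (two) {
      tibble(v = v, branch = c("low", "high"), clbs = c(lo, hi),
             stable = TRUE)
    } else {
      tibble(v = v, branch = "high", clbs = hi, stable = TRUE)
    }
  })
  if (n_starts > 0) {
    set.seed(seed)
    extra <- purrr::map_dfr(v_grid, function(v) {
      ends <- vapply(seq_len(n_starts), function(i) {
        final_clbs(v, "random", clbs0 = runif(1, 0, 200 * v),
                   whi5_frac = runif(1))
      }, numeric(1))
      tibble(v = v, endpoint = ends)
    })
    attr(rows, "multistart") <- extra
  }

  bisect <- function(lo, hi, f) { # f TRUE at lo, FALSE at hi
    while (hi - lo > fold_tol) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  vv <- rows %>% group_by(.data$v) %>% summarise(n = n())
  v_two <- vv$v[vv$n == 2]
  fold_right <- if (length(v_two) > 0 && max(v_two) < max(v_grid)) {
    lo <- max(v_two); hi <- min(v_grid[v_grid > lo])
    bisect(lo, hi, two_at)
  } else NA_real_
  fold_left <- if (length(v_two) > 0 && min(v_two) > min(v_grid)) {
    hi <- min(v_two); lo <- max(v_grid[v_grid < hi])
    # bistability holds above the left fold: bisect on the mirrored axis
    -bisect(-hi, -lo, function(nv) two_at(-nv))
  } else NA_real_

  out <- rows
  attr(out, "fold_left") <- fold_left
  attr(out, "fold_right") <- fold_right
  attr(out, "model") <- model
  class(out) <- c("bifurcation_scan", class(out))
  out
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat("<bifurcation_scan>", attr(x, "model"), "model;",
      "folds at", format(attr(x, "fold_left")), "and",
      format(attr(x, "fold_right")), "fL\n")
  NextMethod()
}

#' @rdname bifurcation_scan
#' @param x A `bifurcation_scan`.
#' @param ... Unused.
#' @export
glance.bifurcation_scan <- function(x, ...) {
  tibble(fold_left = attr(x, "fold_left"), fold_right = attr(x, "fold_right"),
         n_grid = length(unique(x$v)))
}

#' Lineage statistics by role
#'
#' Means, standard deviations and coefficients of variation of the cell-cycle
#' periods (T1 birth to Start, T2 Start to bud, T_G1 birth to bud, Tb budded
#' phase, Tc full cycle) and of birth volume, per role (mother/daughter),
#' over completed (divided) records.
#'
#' @param records Cell-record tibble ([simulate_lineage()] /
#'   [simulate_cells()]).
#' @param c_vol Volume scale (fL per normalized unit) for `v_birth_fl`.
#' @return Tibble with one row per role and statistic columns.
#' @export
lineage_stats <- function(records, c_vol = 28) {
  div <- records %>% filter(.data$divided)
  if (nrow(div) < 2) abort("need at least 2 completed records")
  div$v_birth_fl <- div$v_birth * c_vol
  div %>%
    select("role", "t1", "t2", "t_g1", "tb", "tc", "v_birth_fl") %>%
    tidyr::pivot_longer(-"role", names_to = "period", values_to = "value") %>%
    group_by(.data$role, .data$period) %>%
    summarise(n = sum(!is.na(.data$value)),
              mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              cv = sd / mean,
              .groups = "drop")
}

#' Two-segment size-control regression
#'
#' Reproduces the size-control analysis: for each cell, `x = ln(V_birth /
#' Vbar_m)` (birth volume relative to the mean mother birth volume) and
#' `y = mu * T_G1`. Cells are binned in `bin_width`-fL intervals of birth
#' volume; bin means are fitted by two straight lines with a free breakpoint
#' (grid search over interior bin boundaries minimizing total SSE) for
#' daughters, or a single line for mothers. A slope of -1 is perfect sizer
#' behaviour; 0 is no size control.
#'
#' @param records Daughter or mother records (divided cells are used).
#' @param mu Specific growth rate (1/min).
#' @param role Role to fit ("daughter" uses the two-segment fit by default).
#' @param bin_width Bin width in fL.
#' @param vbar_m Mean mother birth volume (fL); computed from `records` when
#'   mothers are present, otherwise required.
#' @param c_vol Volume scale (fL).
#' @param two_segment Fit two segments (default for daughters).
#' @return A `size_control_fit` list with `slope1`, `slope2`, `breakpoint`,
#'   `slope_single`, the binned data and the cell-level data.
#' @export
size_control_fit <- function(records, mu = 0.00693, role = "daughter",
                             bin_width = 2, vbar_m = NULL, c_vol = 28,
                             two_segment = role == "daughter") {
  div <- records %>%
    filter(.data$divided, .data$role == !!role, !is.na(.data$t_g1))
  if (nrow(div) < 200)
    abort("need at least 200 completed records for the size-control fit")
  if (is.null(vbar_m)) {
    moms <- records %>% filter(.data$divided, .data$role == "mother")
    if (nrow(moms) == 0)
      abort("supply vbar_m when no mother records are present")
    vbar_m <- mean(moms$v_birth) * c_vol
  }
  dat <- tibble(v_fl = div$v_birth * c_vol,
                x = log(div$v_birth * c_vol / vbar_m),
                y = mu * div$t_g1)
  dat$bin <- floor(dat$v_fl / bin_width) * bin_width + bin_width / 2
  bins <- dat %>%
    group_by(.data$bin) %>%
    summarise(x = mean(.data$x), y = mean(.data$y), n = n()) %>%
    filter(.data$n >= 20) %>%
    arrange(.data$x)
  if (nrow(bins) < 4) abort("too few bins (< 4) for the fit")

  fit_line <- function(d) unname(coef(lm(y ~ x, data = d, weights = d$n)))
  single <- fit_line(bins)

  slope1 <- slope2 <- breakpoint <- NA_real_
  if (two_segment) {
    # segmented (broken-stick) regression on the bin means, weighted by bin
    # occupancy: the two lines are constrained to meet at the breakpoint,
    # which is discovered by a grid search over interior bin boundaries
    # holding at least 10% of the cell mass on each side
    cw <- cumsum(bins$n) / sum(bins$n)
    best <- Inf
    for (i in 2:(nrow(bins) - 2)) {
      if (cw[i] < 0.1 || cw[i] > 0.9) next
      bp <- (bins$x[i] + bins$x[i + 1]) / 2
      h1 <- pmin(bins$x - bp, 0)
      h2 <- pmax(bins$x - bp, 0)
      f <- lm(y ~ h1 + h2, data = bins, weights = bins$n)
      sse <- sum(bins$n * f$residuals^2)
      if (sse < best) {
        best <- sse
        slope1 <- unname(coef(f)[2]); slope2 <- unname(coef(f)[3])
        breakpoint <- bp
      }
    }
  }
  structure(list(role = role, slope1 = slope1, slope2 = slope2,
                 breakpoint = breakpoint, slope_single = single[2],
                 intercept_single = single[1], bins = bins, data = dat,
                 vbar_m = vbar_m, mu = mu),
            class = "size_control_fit")
}

#' @export
print.size_control_fit <- function(x, ...) {
  cat("<size_control_fit>", x$role, "cells\n")
  if (!is.na(x$slope1))
    cat(sprintf("  two-segment slopes %.3f / %.3f, break at ln(V) = %.3f\n",
                x$slope1, x$slope2, x$breakpoint))
  cat(sprintf("  single-line slope %.3f\n", x$slope_single))
  invisible(x)
}

#' @rdname size_control_fit
#' @param x A `size_control_fit`.
#' @param ... Unused.
#' @export
tidy.size_control_fit <- function(x, ...) {
  tibble(term = c("slope_small", "slope_large", "breakpoint", "slope_single"),
         estimate = c(x$slope1, x$slope2, x$breakpoint, x$slope_single))
}

#' @rdname size_control_fit
#' @export
glance.size_control_fit <- function(x, ...) {
  tibble(role = x$role, slope1 = x$slope1, slope2 = x$slope2,
         breakpoint = x$breakpoint, slope_single = x$slope_single,
         n_bins = nrow(x$bins), n_cells = nrow(x$data))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Random cell age for asynchronous-population sampling
#'
#' In an exponentially growing population newborn cells are twice as frequent
#' as dividing cells; the age fraction `theta` of a randomly drawn cell has
#' density `f(theta) = ln(2) 2^(1 - theta)` on \[0, 1\]. `r_async_age()` draws
#' from it by inversion (`theta = 1 - log2(1 + u)`); `d_async_age()` is the
#' density.
#'
#' @param n Number of draws.
#' @return Numeric vector of age fractions in \[0, 1\].
#' @export
r_async_age <- function(n) 1 - log2(1 + runif(n))

#' @rdname r_async_age
#' @param theta Age fraction(s).
#' @export
d_async_age <- function(theta) log(2) * 2^(1 - theta)

#' Asynchronous-population sample from lineage records
#'
#' Each completed cell was sampled (during simulation) at one random age drawn
#' from the asynchronous-population age density; this function extracts those
#' per-cell snapshots: molecule numbers of the class-1 proteins plus the
#' (constant-total) abundances implied by the sampled volume.
#'
#' @param records Cell-record tibble with sampled-age columns.
#' @param params Parameter vector (for the constant totals).
#' @return Tibble of per-cell sampled molecule numbers.
#' @export
async_sample <- function(records, params = cellcycle_params()) {
  s <- records %>% filter(.data$divided, !is.na(.data$theta))
  phi <- 0.6 * s$v_sample * params[["c_vol"]]
  tibble(role = s$role, theta = s$theta,
         v_fl = s$v_sample * params[["c_vol"]],
         cln3 = s$n_cln3, bck2 = s$n_bck2, cln1_cln2 = s$n_cln2,
         clb5_clb6 = s$n_clb5_t, clb1_clb2 = s$n_clb2_t, cki = s$n_cki_t,
         swi5 = s$n_swi5_t, cdc20 = s$n_cdc20_t, pds1 = s$n_pds1_t,
         polo = s$n_polo_t,
         whi5 = params[["whi5_t"]] * 22 * phi,
         net1 = params[["net1_t"]] * 18 * phi,
         ppx = params[["ppx_t"]] * 100 * phi,
         tem1 = params[["tem1_t"]] * 8 * phi,
         cdc15 = params[["cdc15_t"]] * 8 * phi)
}

#' Mean protein abundances of an asynchronous population
#'
#' Averages the per-cell sampled molecule numbers over the population, per
#' protein grouping (lumped paralogues reported under their usual joint
#' names).
#'
#' @param samples Tibble from [async_sample()] (needs >= 500 cells for stable
#'   estimates; fewer are allowed with a warning).
#' @return Tibble `protein`, `mean_molecules`.
#' @export
population_abundances <- function(samples) {
  if (nrow(samples) < 500)
    warning("fewer than 500 sampled cells; abundance estimates will be noisy")
  cols <- c("cln3", "cln1_cln2", "clb5_clb6", "clb1_clb2", "cki", "whi5",
            "net1", "ppx", "tem1", "cdc15")
  tibble(protein = cols,
         mean_molecules = vapply(cols, function(cc) mean(samples[[cc]]),
                                 numeric(1)))
}

#' Simulate an exponentially growing population
#'
#' Every division spawns both mother and daughter; a random thinning keeps
#' the live population below `cap` live cells, with weights scaled so that
#' weighted counts remain unbiased.
#'
#' @param net Network (possibly mutated).
#' @param n_founders Founder cells (all start from the newborn G1 state).
#' @param horizon Absolute end time (min).
#' @param cap Live-population cap.
#' @param stochastic,mode,seed,dt As in [simulate_lineage()].
#' @param cell_horizon Per-cell division cutoff (min).
#' @return Tibble: `gen`, `role`, `t_birth`, `t_div`, `divided`, `weight`,
#'   `tc` (cycle time; NA when censored).
#' @export
simulate_population <- function(net = build_cellcycle_scm(), n_founders = 50,
                                horizon = 600, cap = 2000,
                                stochastic = TRUE,
                                mode = c("full", "no-mrna", "extrinsic"),
                                seed = 1L, dt = 0.01, cell_horizon = 1000) {
  mode <- match.arg(mode)
  simulate_pedigree(net, n_gen = 1000L, n_founders = n_founders,
                    t_horizon = horizon, cap = cap, stochastic = stochastic,
                    mode = mode, seed = seed, dt = dt,
                    cell_horizon = cell_horizon, burn_in = 0)
}

#' Growth curve and cycle-time survival of a population
#'
#' From population records, computes the weighted number of live cells over
#' time with a fitted number-doubling time (ndt), and the cycle-time survival
#' function `P(t)` — the probability that a cell's cycle time exceeds `t` —
#' with never-dividing cells treated as censored at the horizon (only cells
#' whose observation window covers `t` enter the estimate at `t`).
#'
#' @param pop Tibble from [simulate_population()].
#' @param horizon Observation horizon used in the simulation (min).
#' @param t_grid Evaluation grid for `P(t)` and the growth curve.
#' @return List with `growth` (tibble `t`, `n_cells`), `ndt` (min),
#'   `survival` (tibble `t`, `p_greater`).
#' @export
growth_and_survival <- function(pop, horizon = max(pop$t_birth, na.rm = TRUE),
                                t_grid = seq(0, horizon, by = 10)) {
  n_at <- vapply(t_grid, function(tt) {
    alive <- pop$t_birth <= tt & (!pop$divided | pop$t_div > tt)
    sum(pop$weight[alive])
  }, numeric(1))
  growth <- tibble(t = t_grid, n_cells = n_at)
  pos <- growth %>% filter(.data$n_cells > 0)
  ndt <- if (nrow(pos) >= 3) {
    1 / unname(coef(lm(log2(n_cells) ~ t, data = pos))[2])
  } else NA_real_
  surv <- vapply(t_grid, function(tt) {
    eligible <- pop$t_birth <= horizon - tt
    if (!any(eligible)) return(NA_real_)
    w <- pop$weight[eligible]
    over <- !pop$divided[eligible] | pop$tc[eligible] > tt
    sum(w[over]) / sum(w)
  }, numeric(1))
  list(growth = growth, ndt = ndt,
       survival = tibble(t = t_grid, p_greater = surv))
}
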