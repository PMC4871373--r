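#' Parameter set of the Start-transition standard component model
#'
#' Rate constants, interaction coefficients and noise floors of the seven-ODE
#' Start model (Cln3, ClbS, active/total Whi5, the Hi5 phosphatase, total SBF,
#' free SBF). Units: synthesis rates in molecules per fL per min (Cln3 per
#' fL^2), first-order rates in 1/min, interaction coefficients in fL per
#' molecule.
#'
#' @param ... Named overrides of individual parameters.
#' @return Named numeric vector.
#' @export
start_params <- function(...) {
  p <- c(
    ka_g = 0.25, kd_bf = 0.01, kd_bS = 0.1, kd_g = 12, kd_hi5 = 0.01,
    kd_i5 = 0.01, kd_mbS = 0.25, kd_mhi5 = 0.7, kd_mi5 = 0.7, kd_mn3 = 1,
    kd_n3 = 0.14, ks_bf = 1.53, ks_bS = 0.3, ks_hi5 = 0.1275, ks_i5 = 0.715,
    ks_mbS = 11.5, ks_mhi5 = 7, ks_mi5 = 5.25, ks_mn3 = 7.5, ks_n3 = 0.0024,
    mmin_bS = 1, mmin_hi5 = 0, mmin_i5 = 0, mmin_n3 = 0,
    gamma = 0.15, mu = 0.007, sigma = 0.1,
    om_dp = 0.12, om_p = 6.2, om_pp = 0.33
  )
  override_params(p, list(...), "Start model")
}

override_params <- function(p, dots, label) {
  if (length(dots) == 0) return(p)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0)
    abort(paste0("unknown ", label, " parameter(s): ",
                 paste(bad, collapse = ", ")))
  p[names(dots)] <- unlist(dots)
  p
}

#' Initial conditions of the Start model
#'
#' Newborn-cell initial state at `v0` fL: Cln3, ClbS and free SBF start at
#' zero; Whi5 (all active), Hi5 and total SBF start at the steady-state levels
#' implied by their constitutive synthesis/degradation balance at `v0`
#' (at 10 fL: Hi5 = 1275, SBF_T = 1530, Whi5 = 5363 molecules).
#'
#' @param params Parameter vector from [start_params()].
#' @param v0 Initial volume in fL.
#' @return Named numeric vector `cln3, clbs, whi5_a, whi5_t, hi5, sbf_t`.
#' @export
start_init <- function(params = start_params(), v0 = 10) {
  p <- params
  whi5 <- p[["ks_i5"]] * v0 * (p[["ks_mi5"]] / p[["kd_mi5"]]) / p[["kd_i5"]]
  hi5 <- p[["ks_hi5"]] * v0 * (p[["ks_mhi5"]] / p[["kd_mhi5"]]) / p[["kd_hi5"]]
  sbft <- p[["ks_bf"]] * v0 / p[["kd_bf"]]
  c(cln3 = 0, clbs = 0, whi5_a = whi5, whi5_t = whi5, hi5 = hi5, sbf_t = sbft)
}

#' Build the Start-transition SCM as a declarative network
#'
#' Constructs the [network_spec()] for the Start model: class-1 totals Cln3
#' (synthesis proportional to V^2), ClbS (SBF-driven promoter factor), total
#' Whi5, Hi5 and total SBF; the class-2 active-Whi5 variable with
#' phosphorylation by Cln3/ClbS opposed by Hi5; and the class-3 free-SBF rule
#' `SBF = max(0, SBF_T - Whi5_A)`. mRNA factors are frozen at their
#' steady-state levels `k_s,m / k_d,m`.
#'
#' @param params Parameter vector from [start_params()].
#' @param v0 Initial volume (fL).
#' @return A `network_spec` with engine `"start"`.
#' @export
build_start_scm <- function(params = start_params(), v0 = 10) {
  required <- names(start_params())
  missing <- setdiff(required, names(params))
  if (length(missing) > 0)
    abort(paste0("missing Start model parameter(s): ",
                 paste(missing, collapse = ", ")))
  p <- as.list(params)
  init <- start_init(params, v0)
  ga <- function(state, v) {
    sbf <- state[["sbf"]]
    c(ga = sbf / (sbf + p$kd_g * v / p$ka_g))
  }
  species <- list(
    class1_spec("cln3",
      synthesis = list(rate_term(p$ks_n3 * p$ks_mn3 / p$kd_mn3, v_exp = 2)),
      degradation = list(rate_term(p$kd_n3)),
      init = init[["cln3"]]),
    class1_spec("whi5_t",
      synthesis = list(rate_term(p$ks_i5 * p$ks_mi5 / p$kd_mi5, v_exp = 1)),
      degradation = list(rate_term(p$kd_i5)),
      init = init[["whi5_t"]]),
    class1_spec("hi5",
      synthesis = list(rate_term(p$ks_hi5 * p$ks_mhi5 / p$kd_mhi5, v_exp = 1)),
      degradation = list(rate_term(p$kd_hi5)),
      init = init[["hi5"]]),
    class1_spec("sbf_t",
      synthesis = list(rate_term(p$ks_bf, v_exp = 1)),
      degradation = list(rate_term(p$kd_bf)),
      init = init[["sbf_t"]]),
    class2_spec("whi5_a", total = "whi5_t", gamma = p$gamma, sigma = p$sigma,
      pos = c(hi5 = p$om_dp), neg = c(cln3 = p$om_p, clbs = p$om_pp),
      per_volume = TRUE, init = init[["whi5_a"]]),
    class3_spec("sbf", kind = "single", operands = c("sbf_t", "whi5_a")),
    class3_spec("ga", kind = "custom", fn = ga),
    class1_spec("clbs",
      synthesis = list(rate_term(p$ks_bS * p$ks_mbS / p$kd_mbS,
                                 regulators = "ga", v_exp = 1)),
      degradation = list(rate_term(p$kd_bS)),
      init = init[["clbs"]])
  )
  network_spec(species, growth_law(v0 = v0, mu = p$mu), params = params,
               engine = "start")
}

#' Simulate the Start model (compiled fast path)
#'
#' Integrates the Start SCM by explicit Euler with step `dt`, either
#' deterministically or with the chemical-Langevin noise layer. `mode` selects
#' the stochastic treatment: lumped mRNA-inherited noise (the default
#' stochastic form), protein noise only, or explicit CLE mRNA species.
#'
#' @param params Parameter vector from [start_params()].
#' @param v0 Initial volume (fL).
#' @param tend End time (min).
#' @param dt Euler step (min).
#' @param record_dt Output cadence (min).
#' @param stochastic Logical; add Langevin noise.
#' @param mode For stochastic runs: "mrna" (lumped mRNA noise), "protein-only",
#'   or "explicit-mrna".
#' @param seed Integer seed for the stochastic path.
#' @param fixed_v Freeze the volume.
#' @param init Optional named initial state overriding [start_init()].
#' @return Tibble with `t`, `v`, molecule numbers of all species, free `sbf`,
#'   and nM concentrations `sbf_nm`, `clbs_nm`.
#' @export
simulate_start <- function(params = start_params(), v0 = 10, tend = 300,
                           dt = 0.01, record_dt = 0.1, stochastic = FALSE,
                           mode = c("mrna", "protein-only", "explicit-mrna"),
                           seed = 1L, fixed_v = FALSE, init = NULL) {
  mode <- match.arg(mode)
  imode <- if (!stochastic) 0L else switch(mode, mrna = 1L,
                                           `protein-only` = 2L,
                                           `explicit-mrna` = 3L)
  x0 <- start_init(params, v0)
  if (!is.null(init)) x0[names(init)] <- init
  x0v <- unname(x0[c("cln3", "clbs", "whi5_a", "whi5_t", "hi5", "sbf_t")])
  if (imode == 3L) {
    p <- params
    x0v <- c(x0v, p[["ks_mn3"]] / p[["kd_mn3"]], 0,
             p[["ks_mi5"]] / p[["kd_mi5"]], p[["ks_mhi5"]] / p[["kd_mhi5"]])
  }
  m <- start_sim_cpp(params, x0v, v0, tend, dt, record_dt, imode, fixed_v,
                     as.integer(seed))
  cols <- c("t", "v", "cln3", "clbs", "whi5_a", "whi5_t", "hi5", "sbf_t")
  if (imode == 3L) cols <- c(cols, "m_n3", "m_bs", "m_i5", "m_hi5")
  cols <- c(cols, "sbf")
  colnames(m) <- cols
  out <- as_tibble(as.data.frame(m))
  out$sbf_nm <- number_to_concentration(out$sbf, out$v)
  out$clbs_nm <- number_to_concentration(out$clbs, out$v)
  out
}

#' First upcrossing of a concentration threshold
#'
#' Finds the first time at which a species' concentration rises through a
#' threshold, with linear interpolation between stored output points. With
#' `v_aware = TRUE` (default) the species column holds molecule numbers and is
#' converted to nM with the instantaneous volume column `v`; otherwise the
#' column is compared to the threshold as-is.
#'
#' @param traj Trajectory tibble with columns `t`, `v` and `species`.
#' @param species Column name to monitor.
#' @param threshold Threshold (nM if `v_aware`).
#' @param v_aware Convert numbers to concentration before comparing.
#' @return Crossing time in min, or `NA_real_` if the threshold is never
#'   reached.
#' @export
detect_first_crossing <- function(traj, species, threshold, v_aware = TRUE) {
  if (nrow(traj) == 0) abort("empty trajectory")
  y <- traj[[species]]
  if (v_aware) y <- number_to_concentration(y, traj$v)
  above <- y >= threshold
  if (above[1]) return(traj$t[1])
  idx <- which(!above[-length(above)] & above[-1])
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  f <- (threshold - y[i]) / (y[i + 1] - y[i])
  traj$t[i] + f * (traj$t[i + 1] - traj$t[i])
}

#' Start and G1/S transition times of a Start-model trajectory
#'
#' The Start transition is the first time free SBF concentration rises above
#' 15 nM; the G1/S transition the first time ClbS concentration rises above
#' 37.5 nM. Thresholds are 50% of the maximum concentrations of the original
#' multisite-phosphorylation study.
#'
#' @param traj Tibble from [simulate_start()] (or [simulate_multip()], whose
#'   columns are mapped onto `sbf`/`clbs`).
#' @param sbf_threshold,clbs_threshold Thresholds in nM.
#' @return One-row tibble with `t1` (Start), `t_g1` (G1/S) and `t2 = t_g1 - t1`.
#' @export
start_transition_times <- function(traj, sbf_threshold = 15,
                                   clbs_threshold = 37.5) {
  t1 <- detect_first_crossing(traj, "sbf", sbf_threshold)
  tg1 <- detect_first_crossing(traj, "clbs", clbs_threshold)
  tibble(t1 = t1, t_g1 = tg1, t2 = tg1 - t1)
}

#' Transition timing as a function of birth size
#'
#' Runs one deterministic simulation per initial volume and reports the Start
#' (`t1`) and G1/S (`t_g1`) times. Both decrease with increasing birth size;
#' the gap `t2` is nearly independent of it.
#'
#' @param v0_grid Vector of initial volumes (fL), all positive.
#' @param model "scm" or "multip".
#' @param params Parameter vector for the chosen model.
#' @param tend,dt Integration settings.
#' @return Tibble with columns `v0`, `t1`, `t_g1`, `t2`.
#' @export
timing_vs_birth_size <- function(v0_grid, model = c("scm", "multip"),
                                 params = NULL, tend = 500, dt = 0.01) {
  model <- match.arg(model)
  if (any(v0_grid <= 0)) abort("initial volumes must be positive")
  if (is.null(params))
    params <- if (model == "scm") start_params() else multip_params()
  purrr::map_dfr(v0_grid, function(v0) {
    traj <- if (model == "scm")
      simulate_start(params, v0 = v0, tend = tend, dt = dt)
    else
      simulate_multip(params, v0 = v0, tend = tend, dt = dt)
    tt <- start_transition_times(traj)
    tibble(v0 = v0, t1 = tt$t1, t_g1 = tt$t_g1, t2 = tt$t2)
  })
}
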