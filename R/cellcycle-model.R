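.cc_state_names <- c(
  "cln3", "bck2", "cln2", "whi5_a", "sbf_a", "bud", "clb5_t", "clb2_t",
  "cki_t", "cki_p", "swi5_t", "ori", "cdh1_a", "apc_p", "mad2_a", "spn",
  "cdc20_t", "pds1_t", "ppx_a", "net1_a", "polo_t", "polo_a", "tem1_a",
  "cdc15_a")

.cc_derived_names <- c(
  "sbf", "clb5", "clb2", "cdc20_a", "cdc20_apc_p", "cdc20_apc", "esp1",
  "cdc14", "swi5_a", "mcm1_a", "tem1_cdc15")

.cc_class1 <- c("cln3", "bck2", "cln2", "clb5_t", "clb2_t", "cki_t",
                "swi5_t", "cdc20_t", "pds1_t", "polo_t")

# characteristic concentrations (nM) of the class-1 proteins, same order
.cc_cs <- c(cln3 = 40, bck2 = 40, cln2 = 40, clb5_t = 40, clb2_t = 40,
            cki_t = 40, swi5_t = 57.5, cdc20_t = 150, pds1_t = 3.3,
            polo_t = 100)

.cc_record_names <- c(
  "gen", "role", "t_birth", "v_birth", "t_start", "t_bud", "t_ori", "t_spn",
  "t_div", "v_div", "divided", "sbf_max", "theta", "v_sample",
  paste0("n_", .cc_class1))

#' Parameter set of the full cell-cycle model (wild type)
#'
#' The ~125 rate constants, interaction coefficients, total concentrations and
#' thresholds of the full budding-yeast cell-cycle SCM, in normalized
#' concentration units, plus the extra parameters of the stochastic layer
#' (`k_flag` division-hysteresis threshold, translation rate `k_tr`, mRNA
#' turnover `k_dm`, per-gene mRNA floors `mmin_*`, division-fraction noise
#' `div_sd` and the volume scale `c_vol` = 28 fL). `medium` sets the specific
#' growth rate: glucose (mdt 100 min) or galactose/raffinose (mdt 150 min).
#'
#' @param medium "glucose" or "raffinose" (galactose has the same growth rate).
#' @param ... Named overrides.
#' @return Named numeric vector.
#' @export
cellcycle_params <- function(medium = c("glucose", "raffinose", "galactose"),
                             ...) {
  medium <- match.arg(medium)
  p <- c(
    ks_bck2 = 0.00675, kd_bck2 = 0.5, ks_bud_e = 0.33, kd_bud = 0.01,
    ks_cdc20 = 0.006, ks_cdc20_m1 = 0.6, kd_cdc20 = 0.3,
    ks_cki = 0.024, ks_cki_swi5 = 0.24, kd_cki = 0.005, kd_ckip = 1.7,
    ks_cki_gal = 0,
    ks_clb2 = 0.0066, ks_clb2_m1 = 0.044, kd_clb2 = 0.003, kd_clb2_20 = 0.14,
    kd_clb2_20_i = 0.0366, kd_clb2_h1 = 0.6,
    ks_clb5 = 0.0006, ks_clb5_bf = 0.029, kd_clb5 = 0.012, kd_clb5_20 = 0.1,
    kd_clb5_20_i = 0.015,
    ks_cln2 = 0, ks_cln2_bf = 0.27, kd_cln2 = 0.12,
    ks_cln3 = 0.11, kd_cln3 = 0.4,
    ks_ori_e = 2, kd_ori = 0.06,
    ks_pds1 = 0.03, kd_pds1 = 0.05, kd_pds1_20 = 3, kd_pds1_20_i = 0.3,
    ks_polo_m1 = 0.03, kd_polo = 0.01, kd_polo_h1 = 0.1,
    ks_swi5 = 0.005, ks_swi5_m1 = 0.08, kd_swi5 = 0.08,
    ks_spn = 0.1, kd_spn = 0.06,
    mu = 0.00693, gamma = 1, gamma_cki = 2, gamma_apc = 0.8, gamma_tem1 = 0.1,
    om_a_apc_b2 = 0.65, om_i_apc = 1,
    om_a_cdc15_14 = 15, om_i_cdc15 = 1, om_i_cdc15_b2 = 0.25,
    om_a_cdh1 = 1, om_a_cdh1_14 = 4.3, om_i_cdh1_e = 1, om_i_cdh1_n3 = 1,
    om_i_cdh1_n2 = 0.6222, om_i_cdh1_b5 = 4.5, om_i_cdh1_b2 = 2.8,
    om_p_cki_n3 = 4.2, om_p_cki_k2 = 0.4, om_p_cki_n2 = 0.3556,
    om_p_cki_b5 = 1.5, om_p_cki_b2 = 2.2, om_dp_cki = 1, om_dp_cki_14 = 1.8,
    om_a_mad2 = 20, om_i_mad2 = 0.4,
    om_a_mcm1_b2 = 5, om_i_mcm1 = 3,
    om_p_net1_b2 = 0.125, om_p_net1_en = 1, om_p_net1_15 = 0.03,
    om_dp_net1 = 0.1, om_dp_net1_14 = 0.1, om_dp_net1_px = 3,
    om_a_polo_b2 = 5, om_i_polo = 1,
    om_a_ppx = 1, om_i_ppx_p1 = 3,
    om_p_sbf_b2 = 2.5, om_dp_sbf = 1,
    om_a_swi5_14 = 2, om_i_swi5_b2 = 4.25,
    om_a_tem1_lo = 6, om_i_tem1 = 1, om_i_tem1_px = 22,
    om_p_whi5_n2 = 1.7778, om_p_whi5_n3 = 12, om_p_whi5_k2 = 16,
    om_p_whi5_b5 = 0, om_dp_whi5 = 1, om_dp_whi5_14 = 0.5,
    apc_t = 25, cdc14_t = 2, cdc15_t = 1, cdh1_t = 1, esp1_t = 0.5,
    mcm1_t = 1, net1_t = 3.55, ppx_t = 1, sbf_t = 1, tem1_t = 2,
    whi5_t = 2.5, mad2_t = 25,
    d_cln3 = 1, e_bud_b5 = 0.25, e_bud_n2 = 0.4444, e_bud_n3 = 0.2,
    e_ori_b2 = 0.35, e_ori_b5 = 0.21, j_cln3 = 6, j_spn = 0.26,
    k_ez = 0.4, k_ez2 = 0.4, rho_14_net1 = 1, sigma = 10, sigma_net1 = 8,
    k_flag = 0.8, k_tr = 0.15, k_dm = 0.7, div_sd = 0.05, c_vol = 28,
    mmin_cln3 = 0, mmin_bck2 = 0, mmin_cln2 = 5, mmin_clb5 = 5,
    mmin_clb2 = 5, mmin_cki = 5, mmin_swi5 = 0, mmin_cdc20 = 0,
    mmin_pds1 = 5, mmin_polo = 0
  )
  if (medium != "glucose") p[["mu"]] <- log(2) / 150
  override_params(p, list(...), "cell-cycle model")
}

#' Initial state of the full cell-cycle model
#'
#' Normalized-concentration initial values of a newborn G1 daughter cell
#' (`v_n` = 1.1460, i.e. about 32 fL). The class-3 values are recomputed from
#' their defining identities at t = 0 rather than taken at face value, and the
#' event flags start as a licensed, unbudded G1 cell (`b_oriflag` = 1,
#' `b_udna` = `b_spc` = 0).
#'
#' @return List with `state` (named vector, 24 dynamic variables) and `v_n`.
#' @export
cellcycle_init <- function() {
  state <- c(
    cln3 = 0.0757, bck2 = 0.0308, cln2 = 0.1343, whi5_a = 1.7238,
    sbf_a = 0.6560, bud = 0.0488, clb5_t = 0.3752, clb2_t = 0.2687,
    cki_t = 0.4012, cki_p = 0, swi5_t = 0.6333, ori = 0.0710,
    cdh1_a = 0.9574, apc_p = 0.1216, mad2_a = 0.4497, spn = 0.0389,
    cdc20_t = 1.2422, pds1_t = 0.0294, ppx_a = 0.0128, net1_a = 0.1086,
    polo_t = 0.2915, polo_a = 0.2073, tem1_a = 0.8592, cdc15_a = 0.9823)
  list(state = state, v_n = 1.1460)
}

#' Build the full cell-cycle SCM
#'
#' Assembles the declarative network of the full model (used by the generic
#' reference integrator and as the mutable object for mutant overrides) and
#' binds the compiled engine used by [simulate_cellcycle()] and
#' [simulate_lineage()]. The network holds the parameter vector, initial
#' state and growth law; event rules and division are properties of the
#' simulators, not of the ODE right-hand side.
#'
#' @param params Vector from [cellcycle_params()].
#' @param init List from [cellcycle_init()].
#' @return A `network_spec` with engine `"cellcycle"`.
#' @export
build_cellcycle_scm <- function(params = cellcycle_params(),
                                init = cellcycle_init()) {
  required <- names(cellcycle_params())
  missing <- setdiff(required, names(params))
  if (length(missing) > 0)
    abort(paste0("missing cell-cycle parameter(s): ",
                 paste(missing, collapse = ", ")))
  p <- as.list(params)
  s0 <- init$state
  cln3_drive <- function(state, v) {
    c(cln3_drive = p$d_cln3 * v / (p$j_cln3 + p$d_cln3 * v))
  }
  heav_spn <- function(state, v) {
    c(heav_spn = hard_heaviside(state[["clb2"]] - p$j_spn))
  }
  species <- list(
    # quasi-steady class-2 activities (evaluated first in the algebraic pass)
    class2_spec("swi5_a", total = "swi5_t", gamma = p$gamma, sigma = p$sigma,
      pos = c(cdc14 = p$om_a_swi5_14), neg = c(clb2 = p$om_i_swi5_b2),
      qss = TRUE, init = s0[["swi5_t"]]),
    class2_spec("mcm1_a", total = p$mcm1_t, gamma = p$gamma, sigma = p$sigma,
      pos = c(clb2 = p$om_a_mcm1_b2), w0 = -p$om_i_mcm1, qss = TRUE),
    # class-3 chain in topological order
    class3_spec("sbf", kind = "single", operands = c("sbf_a", "whi5_a")),
    class3_spec(c("clb5", "clb2"), kind = "shared",
                operands = c("clb5_t", "clb2_t", "cki_t")),
    class3_spec("cdc20_a", kind = "single",
                operands = c("cdc20_t", "mad2_a")),
    class3_spec("cdc20_apc_p", kind = "min",
                operands = c("cdc20_a", "apc_p")),
    class3_spec("cdc20_apc", kind = "custom", fn = function(state, v) {
      c(cdc20_apc = min(state[["cdc20_a"]] - state[["cdc20_apc_p"]],
                        p$apc_t - state[["apc_p"]]))
    }),
    class3_spec("esp1", kind = "custom", fn = function(state, v) {
      c(esp1 = max(0, p$esp1_t - state[["pds1_t"]]))
    }),
    class3_spec("cdc14", kind = "custom", fn = function(state, v) {
      c(cdc14 = max(0, p$cdc14_t - p$rho_14_net1 * state[["net1_a"]]))
    }),
    class3_spec("tem1_cdc15", kind = "min",
                operands = c("tem1_a", "cdc15_a")),
    class3_spec("cln3_drive", kind = "custom", fn = cln3_drive),
    class3_spec("heav_spn", kind = "custom", fn = heav_spn),
    # class-1 totals
    class1_spec("cln3",
      synthesis = list(rate_term(p$ks_cln3, "cln3_drive")),
      degradation = list(rate_term(p$kd_cln3)), init = s0[["cln3"]]),
    class1_spec("bck2",
      synthesis = list(rate_term(p$ks_bck2, v_exp = 1)),
      degradation = list(rate_term(p$kd_bck2)), init = s0[["bck2"]]),
    class1_spec("cln2",
      synthesis = list(rate_term(p$ks_cln2), rate_term(p$ks_cln2_bf, "sbf")),
      degradation = list(rate_term(p$kd_cln2)), init = s0[["cln2"]]),
    class1_spec("clb5_t",
      synthesis = list(rate_term(p$ks_clb5), rate_term(p$ks_clb5_bf, "sbf")),
      degradation = list(rate_term(p$kd_clb5),
                         rate_term(p$kd_clb5_20, "cdc20_apc_p"),
                         rate_term(p$kd_clb5_20_i, "cdc20_apc")),
      init = s0[["clb5_t"]]),
    class1_spec("clb2_t",
      synthesis = list(rate_term(p$ks_clb2, v_exp = 1),
                       rate_term(p$ks_clb2_m1, "mcm1_a", v_exp = 1)),
      degradation = list(rate_term(p$kd_clb2),
                         rate_term(p$kd_clb2_20, "cdc20_apc_p"),
                         rate_term(p$kd_clb2_20_i, "cdc20_apc"),
                         rate_term(p$kd_clb2_h1, "cdh1_a")),
      init = s0[["clb2_t"]]),
    # effective CKI decay: unphosphorylated pool at kd_cki, phosphorylated at
    # the much faster kd_ckip, expressed as a state-dependent rate factor
    class3_spec("cki_deg_rate", kind = "custom", fn = function(state, v) {
      frac <- if (state[["cki_t"]] > 1e-12)
        min(1, state[["cki_p"]] / state[["cki_t"]]) else 0
      c(cki_deg_rate = p$kd_cki * (1 - frac) + p$kd_ckip * frac)
    }),
    class1_spec("cki_t",
      synthesis = list(rate_term(p$ks_cki), rate_term(p$ks_cki_swi5, "swi5_a"),
                       rate_term(p$ks_cki_gal)),
      degradation = list(rate_term(1, "cki_deg_rate")),
      init = s0[["cki_t"]]),
    class1_spec("swi5_t",
      synthesis = list(rate_term(p$ks_swi5), rate_term(p$ks_swi5_m1, "mcm1_a")),
      degradation = list(rate_term(p$kd_swi5)), init = s0[["swi5_t"]]),
    class1_spec("cdc20_t",
      synthesis = list(rate_term(p$ks_cdc20),
                       rate_term(p$ks_cdc20_m1, "mcm1_a")),
      degradation = list(rate_term(p$kd_cdc20)), init = s0[["cdc20_t"]]),
    class1_spec("pds1_t",
      synthesis = list(rate_term(p$ks_pds1)),
      degradation = list(rate_term(p$kd_pds1),
                         rate_term(p$kd_pds1_20, "cdc20_apc_p"),
                         rate_term(p$kd_pds1_20_i, "cdc20_apc")),
      init = s0[["pds1_t"]]),
    class1_spec("polo_t",
      synthesis = list(rate_term(p$ks_polo_m1, "mcm1_a")),
      degradation = list(rate_term(p$kd_polo),
                         rate_term(p$kd_polo_h1, "cdh1_a")),
      init = s0[["polo_t"]]),
    # progress variables (class-1-like, no volume factor)
    class1_spec("bud",
      synthesis = list(rate_term(p$ks_bud_e * p$e_bud_n3, "cln3"),
                       rate_term(p$ks_bud_e * p$e_bud_n2, "cln2"),
                       rate_term(p$ks_bud_e * p$e_bud_b5, "clb5")),
      degradation = list(rate_term(p$kd_bud)), init = s0[["bud"]]),
    class1_spec("ori",
      synthesis = list(rate_term(p$ks_ori_e * p$e_ori_b5, "clb5"),
                       rate_term(p$ks_ori_e * p$e_ori_b2, "clb2")),
      degradation = list(rate_term(p$kd_ori)), init = s0[["ori"]]),
    class1_spec("spn",
      synthesis = list(rate_term(p$ks_spn, "heav_spn")),
      degradation = list(rate_term(p$kd_spn)), init = s0[["spn"]]),
    # dynamic class-2 activities
    class2_spec("whi5_a", total = p$whi5_t, gamma = p$gamma, sigma = p$sigma,
      w0 = p$om_dp_whi5,
      pos = c(cdc14 = p$om_dp_whi5_14),
      neg = c(cln3 = p$om_p_whi5_n3, bck2 = p$om_p_whi5_k2,
              cln2 = p$om_p_whi5_n2, clb5 = p$om_p_whi5_b5),
      init = s0[["whi5_a"]]),
    class2_spec("sbf_a", total = p$sbf_t, gamma = p$gamma, sigma = p$sigma,
      w0 = p$om_dp_sbf, neg = c(clb2 = p$om_p_sbf_b2), init = s0[["sbf_a"]]),
    class2_spec("cki_p", total = "cki_t", gamma = p$gamma_cki,
      sigma = p$sigma,
      w0 = -p$om_dp_cki,
      pos = c(cln3 = p$om_p_cki_n3, bck2 = p$om_p_cki_k2,
              cln2 = p$om_p_cki_n2, clb5 = p$om_p_cki_b5,
              clb2 = p$om_p_cki_b2),
      neg = c(cdc14 = p$om_dp_cki_14),
      extra_deg = p$kd_ckip, init = s0[["cki_p"]]),
    class2_spec("cdh1_a", total = p$cdh1_t, gamma = p$gamma, sigma = p$sigma,
      w0 = p$om_a_cdh1,
      pos = c(cdc14 = p$om_a_cdh1_14),
      neg = c(cln3 = p$om_i_cdh1_e * p$om_i_cdh1_n3,
              cln2 = p$om_i_cdh1_e * p$om_i_cdh1_n2,
              clb5 = p$om_i_cdh1_e * p$om_i_cdh1_b5,
              clb2 = p$om_i_cdh1_e * p$om_i_cdh1_b2),
      init = s0[["cdh1_a"]]),
    class2_spec("apc_p", total = p$apc_t, gamma = p$gamma_apc,
      sigma = p$sigma, w0 = -p$om_i_apc,
      pos = c(clb2 = p$om_a_apc_b2), init = s0[["apc_p"]]),
    class2_spec("mad2_a", total = p$mad2_t, gamma = p$gamma, sigma = p$sigma,
      w0 = -p$om_i_mad2, pos = c(mad2_drive = p$om_a_mad2),
      init = s0[["mad2_a"]]),
    class2_spec("ppx_a", total = p$ppx_t, gamma = p$gamma, sigma = p$sigma,
      w0 = p$om_a_ppx, neg = c(esp1 = p$om_i_ppx_p1), init = s0[["ppx_a"]]),
    class2_spec("net1_a", total = p$net1_t, gamma = p$gamma,
      sigma = p$sigma_net1, w0 = p$om_dp_net1,
      pos = c(cdc14 = p$om_dp_net1_14, ppx_a = p$om_dp_net1_px),
      neg = c(clb2 = p$om_p_net1_b2, tem1_cdc15 = p$om_p_net1_en,
              cdc15_free = p$om_p_net1_15),
      init = s0[["net1_a"]]),
    class3_spec("cdc15_free", kind = "custom", fn = function(state, v) {
      c(cdc15_free = state[["cdc15_a"]] - state[["tem1_cdc15"]])
    }),
    class2_spec("polo_a", total = "polo_t", gamma = p$gamma, sigma = p$sigma,
      w0 = -p$om_i_polo, pos = c(clb2 = p$om_a_polo_b2),
      init = s0[["polo_a"]]),
    class2_spec("tem1_a", total = p$tem1_t, gamma = p$gamma_tem1,
      sigma = p$sigma, w0 = -p$om_i_tem1,
      pos = c(polo_a = p$om_a_tem1_lo), neg = c(ppx_a = p$om_i_tem1_px),
      init = s0[["tem1_a"]]),
    class2_spec("cdc15_a", total = p$cdc15_t, gamma = p$gamma,
      sigma = p$sigma, w0 = -p$om_i_cdc15,
      pos = c(cdc14 = p$om_a_cdc15_14), neg = c(clb2 = p$om_i_cdc15_b2),
      init = s0[["cdc15_a"]]),
    # event flags enter the Mad2 influence; constant within an ODE segment
    class1_spec("mad2_drive", synthesis = list(), degradation = list(),
                init = 0)
  )
  net <- network_spec(species, growth_law(v0 = init$v_n, mu = p$mu),
                      params = params, engine = "cellcycle")
  attr(net, "init") <- init
  net
}

cc_param_vector <- function(net) {
  if (inherits(net, "network_spec")) net$params else net
}

cc_init_vector <- function(net, init = NULL) {
  if (is.null(init)) init <- attr(net, "init")
  if (is.null(init)) init <- cellcycle_init()
  init
}

#' Simulate one continuous segment of the full model
#'
#' Integrates the full cell-cycle model without division bookkeeping (event
#' flags held at the supplied values), mainly for steady-state analysis and
#' cross-checks of the compiled engine against the generic integrator.
#'
#' @param net Network from [build_cellcycle_scm()].
#' @param tend,dt,record_dt Integration settings (min).
#' @param v_n0 Initial normalized volume.
#' @param fixed_v Freeze the volume (growth rate set to zero).
#' @param stochastic,mode,seed Stochastic settings as in [simulate_lineage()].
#' @param init Optional named state overrides.
#' @param b_udna,b_spc Values of the DNA-synthesis and spindle flags.
#' @return Tibble of normalized concentrations (dynamic + derived variables).
#' @export
simulate_cellcycle <- function(net = build_cellcycle_scm(), tend = 200,
                               dt = 0.01, record_dt = 0.1, v_n0 = NULL,
                               fixed_v = FALSE, stochastic = FALSE,
                               mode = c("full", "no-mrna", "extrinsic"),
                               seed = 1L, init = NULL, b_udna = 0,
                               b_spc = 0) {
  mode <- match.arg(mode)
  imode <- if (!stochastic) 0L else switch(mode, full = 1L, `no-mrna` = 2L,
                                           extrinsic = 3L)
  ini <- cc_init_vector(net)
  s0 <- ini$state
  if (!is.null(init)) s0[names(init)] <- init
  if (is.null(v_n0)) v_n0 <- ini$v_n
  m <- cc_segment_cpp(cc_param_vector(net), unname(s0[.cc_state_names]),
                      v_n0, tend, dt, record_dt, fixed_v, imode,
                      as.integer(seed), b_udna, b_spc)
  colnames(m) <- c("t", "v_n", .cc_state_names, .cc_derived_names)
  as_tibble(as.data.frame(m))
}

#' Event rules of the full model (reference implementation)
#'
#' Applies the five event rules to a pair of consecutive states: (1) bud
#' emergence when the BUD progress variable reaches 1; (2) onset of DNA
#' synthesis when ORI reaches 1 while origins are licensed, which unlicenses
#' them and raises the unreplicated-DNA flag; (3) spindle-assembly completion
#' when SPN reaches 1; (5) origin relicensing when Clb2 + Clb5 drops below
#' `k_ez2`, resetting ORI; (4) division when Clb2 downcrosses `k_ez`
#' (subject to the `k_flag` hysteresis gate when `gate = TRUE`), resetting
#' BUD, SPN and both flags. Rules are applied in the order 1, 2, 3, 5, 4.
#' The compiled simulators implement identical logic; this R version is the
#' testable reference.
#'
#' @param prev,cur Named numeric vectors with at least `bud`, `ori`, `spn`,
#'   `clb2`, `clb5`.
#' @param flags List with `b_udna`, `b_spc`, `b_oriflag`, `armed`.
#' @param params Parameter vector (uses `k_ez`, `k_ez2`, `k_flag`).
#' @param gate Use the stochastic division hysteresis gate.
#' @return List with updated `cur`, `flags`, and `events` (character vector).
#' @export
apply_event_rules <- function(prev, cur, flags, params = cellcycle_params(),
                              gate = FALSE) {
  ev <- character()
  k_ez <- params[["k_ez"]]; k_ez2 <- params[["k_ez2"]]
  k_flag <- params[["k_flag"]]
  if (prev[["bud"]] < 1 && cur[["bud"]] >= 1) ev <- c(ev, "bud")
  if (flags$b_oriflag == 1 && prev[["ori"]] < 1 && cur[["ori"]] >= 1) {
    ev <- c(ev, "ori")
    flags$b_oriflag <- 0
    flags$b_udna <- 1
  }
  if (flags$b_spc == 0 && prev[["spn"]] < 1 && cur[["spn"]] >= 1) {
    ev <- c(ev, "spn")
    flags$b_spc <- 1
  }
  if (prev[["clb2"]] + prev[["clb5"]] > k_ez2 &&
      cur[["clb2"]] + cur[["clb5"]] <= k_ez2) {
    ev <- c(ev, "relicense")
    cur[["ori"]] <- 0
    flags$b_oriflag <- 1
  }
  if (gate && (prev[["clb2"]] >= k_flag || cur[["clb2"]] >= k_flag))
    flags$armed <- 1
  down <- prev[["clb2"]] > k_ez && cur[["clb2"]] <= k_ez
  if (down && (!gate || flags$armed == 1)) {
    ev <- c(ev, "division")
    cur[["bud"]] <- 0
    cur[["spn"]] <- 0
    flags$b_udna <- 0
    flags$b_spc <- 0
    flags$armed <- 0
  }
  list(cur = cur, flags = flags, events = ev)
}

#' Split a dividing cell between mother and daughter
#'
#' The daughter receives fraction `f` of the volume (and, in molecule-number
#' representations, of every class-1 molecule count, so normalized
#' concentrations are inherited unchanged); the mother keeps `1 - f`. BUD and
#' SPN progress variables and the event flags are reset in both progeny.
#'
#' @param state Named state vector (normalized concentrations).
#' @param v_n Pre-division normalized volume.
#' @param f Daughter fraction in (0, 1).
#' @return List with `daughter` and `mother`, each holding `state` and `v_n`.
#' @export
divide_cell <- function(state, v_n, f) {
  if (f <= 0 || f >= 1) abort("division fraction must lie in (0, 1)")
  reset <- function(s) { s[c("bud", "spn")] <- 0; s }
  list(daughter = list(state = reset(state), v_n = v_n * f),
       mother = list(state = reset(state), v_n = v_n * (1 - f)))
}

cc_records_tibble <- function(m) {
  colnames(m) <- .cc_record_names
  out <- as_tibble(as.data.frame(m))
  out$role <- ifelse(out$role == 1, "mother", "daughter")
  out$t1 <- out$t_start - out$t_birth
  out$t_g1 <- out$t_bud - out$t_birth
  out$t2 <- out$t_bud - out$t_start
  out$tb <- out$t_div - out$t_bud
  out$tc <- out$t_div - out$t_birth
  out$divided <- out$divided == 1
  out
}

#' Simulate a cell lineage through successive divisions
#'
#' Continuous simulation of the full model across divisions, following either
#' the daughter or the mother at each division. Per-cell event times (Start,
#' bud emergence, onset of DNA synthesis, spindle assembly, division) are
#' recorded; the Start time is backfilled per cycle as the first upcrossing
#' of 50% of that cycle's maximum free-SBF level. A cell that fails to divide
#' within `horizon` minutes ends the lineage with `divided = FALSE`.
#'
#' @param net Network from [build_cellcycle_scm()] (or a mutated copy).
#' @param n_divisions Number of divisions to simulate.
#' @param follow "daughter" or "mother".
#' @param stochastic Add the chemical-Langevin noise layer.
#' @param mode "full" (protein + mRNA noise), "no-mrna", or "extrinsic"
#'   (division-fraction noise only).
#' @param seed Integer seed.
#' @param dt Euler step (min).
#' @param horizon Per-cell division cutoff (min).
#' @param record_traj Also return the trajectory.
#' @param record_dt Trajectory cadence (min).
#' @return Tibble of cell records (`gen`, `role`, birth/event times, derived
#'   durations `t1`, `t2`, `t_g1`, `tb`, `tc`, sampled-age molecule numbers);
#'   if `record_traj`, the trajectory tibble is attached as attribute
#'   `"trajectory"`, and the clamp-event fraction as `"clamp_frac"`.
#' @export
simulate_lineage <- function(net = build_cellcycle_scm(), n_divisions = 10,
                             follow = c("daughter", "mother"),
                             stochastic = FALSE,
                             mode = c("full", "no-mrna", "extrinsic"),
                             seed = 1L, dt = 0.01, horizon = 1000,
                             record_traj = FALSE, record_dt = 0.1) {
  follow <- match.arg(follow)
  mode <- match.arg(mode)
  if (n_divisions < 1) abort("n_divisions must be >= 1")
  imode <- if (!stochastic) 0L else switch(mode, full = 1L, `no-mrna` = 2L,
                                           extrinsic = 3L)
  params <- cc_param_vector(net)
  ini <- cc_init_vector(net)
  mdt <- log(2) / params[["mu"]]
  f_mean <- division_fraction(mdt)
  res <- cc_lineage_cpp(params, unname(ini$state[.cc_state_names]), ini$v_n,
                        if (follow == "daughter") 2L else 1L,
                        as.integer(n_divisions), horizon,
                        horizon * (n_divisions + 1), dt, imode,
                        as.integer(seed), record_traj, record_dt, 0.1,
                        f_mean)
  out <- cc_records_tibble(res$records)
  attr(out, "clamp_frac") <- res$clamp_frac
  attr(out, "final_state") <- setNames(res$final_state, .cc_state_names)
  attr(out, "final_v_n") <- res$final_vn
  if (record_traj) {
    traj <- res$trajectory
    colnames(traj) <- c("t", "v_n", .cc_state_names, .cc_derived_names,
                        "b_udna", "b_spc", "b_oriflag")
    attr(out, "trajectory") <- as_tibble(as.data.frame(traj))
  }
  out
}

#' Simulate a growing pedigree (both branches at every division)
#'
#' Every division spawns both the mother and the daughter, each continued as
#' an independent simulation from the division state with its own random
#' stream; the result is the full tree of cells, which is the sampling frame
#' of single-cell microcolony experiments (shorter cycles are represented
#' more often than in a single-lineage stationary distribution). A random
#' thinning caps the live population, scaling weights to keep weighted counts
#' unbiased.
#'
#' @inheritParams simulate_lineage
#' @param n_gen Maximum generation depth.
#' @param n_founders Number of founder cells (all start from the newborn
#'   state of the network).
#' @param t_horizon Absolute simulation horizon (min); `Inf` disables.
#' @param cap Live-population cap.
#' @param cell_horizon Per-cell division cutoff (min).
#' @param burn_in Generations discarded from the returned records (founder
#'   transient); censored (undivided) cells are always kept.
#' @return Cell-record tibble as in [simulate_lineage()], plus `weight`.
#' @export
simulate_pedigree <- function(net = build_cellcycle_scm(), n_gen = 10,
                              n_founders = 2, t_horizon = Inf, cap = 4000,
                              stochastic = TRUE,
                              mode = c("full", "no-mrna", "extrinsic"),
                              seed = 1L, dt = 0.01, cell_horizon = 1000,
                              burn_in = 5) {
  mode <- match.arg(mode)
  imode <- if (!stochastic) 0L else switch(mode, full = 1L, `no-mrna` = 2L,
                                           extrinsic = 3L)
  params <- cc_param_vector(net)
  ini <- cc_init_vector(net)
  f_mean <- division_fraction(log(2) / params[["mu"]])
  if (!is.finite(t_horizon)) t_horizon <- cell_horizon * (n_gen + 1)
  m <- cc_pedigree_cpp(params, unname(ini$state[.cc_state_names]), ini$v_n,
                       as.integer(n_founders), as.integer(n_gen), t_horizon,
                       as.integer(cap), dt, imode, as.integer(seed), f_mean,
                       cell_horizon)
  w <- m[, ncol(m)]
  out <- cc_records_tibble(m[, -ncol(m), drop = FALSE])
  out$weight <- w
  out %>% filter(.data$gen >= burn_in | !.data$divided)
}

#' Simulate many independent lineages
#'
#' Convenience wrapper running `n_lineages` independent copies of
#' [simulate_lineage()] with per-lineage seeds derived from `seed`, binding
#' the records with a `lineage` column. Used to collect large samples of
#' mother or daughter cell cycles.
#'
#' @inheritParams simulate_lineage
#' @param n_lineages Number of independent lineages.
#' @param burn_in Generations discarded from the start of each lineage.
#' @return Tibble of cell records.
#' @export
simulate_cells <- function(net = build_cellcycle_scm(), n_lineages = 25,
                           n_divisions = 25,
                           follow = c("daughter", "mother"),
                           stochastic = TRUE,
                           mode = c("full", "no-mrna", "extrinsic"),
                           seed = 1L, dt = 0.01, horizon = 1000,
                           burn_in = 5) {
  follow <- match.arg(follow)
  mode <- match.arg(mode)
  purrr::map_dfr(seq_len(n_lineages), function(i) {
    r <- simulate_lineage(net, n_divisions = n_divisions, follow = follow,
                          stochastic = stochastic, mode = mode,
                          seed = seed + 7919L * i, dt = dt,
                          horizon = horizon)
    r$lineage <- i
    r
  }) %>%
    filter(.data$gen >= burn_in | !.data$divided)
}
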