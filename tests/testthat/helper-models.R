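# Small shared fixtures built in code.

# a one-species constitutive network: dX/dt = a - b*X
toy_class1_net <- function(a = 2, b = 0.1, mu = 0) {
  network_spec(
    list(class1_spec("x",
                     synthesis = list(rate_term(a)),
                     degradation = list(rate_term(b)), init = 0)),
    growth_law(v0 = 1, mu = mu))
}

# a switch: class-2 activity driven by a constant input
toy_class2_net <- function(gamma, sigma, w0, total = 1) {
  network_spec(
    list(class2_spec("y", total = total, gamma = gamma, sigma = sigma,
                     w0 = w0, init = 0)),
    growth_law(v0 = 1, mu = 0))
}

# synthetic cell records for the analysis helpers
synthetic_records <- function(n, role = "daughter", sizer_slope = -1,
                              mu = 0.00693, noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  v_birth <- exp(rnorm(n, log(1.0), 0.25))            # normalized units
  base <- 0.45                                         # mu*T at V = vbar
  y <- base + sizer_slope * log(v_birth) + rnorm(n, 0, noise_sd)
  t_g1 <- pmax(1, y / mu)
  tibble::tibble(
    gen = 6, role = role, t_birth = 0, v_birth = v_birth,
    t_start = t_g1 * 0.8, t_bud = t_g1, t_ori = t_g1 + 5, t_spn = t_g1 + 40,
    t_div = t_g1 + 60, v_div = v_birth * exp(mu * (t_g1 + 60)),
    divided = TRUE, sbf_max = 1, theta = 0.5, v_sample = v_birth,
    t1 = t_g1 * 0.8, t_g1 = t_g1, t2 = t_g1 * 0.2, tb = 60, tc = t_g1 + 60)
}
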