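#' Noise configuration of the stochastic layer
#'
#' Collects the parameters of the chemical-Langevin layer: the translation
#' rate `k_tr` (protein molecules per mRNA per fL per min) and mRNA turnover
#' `k_dm` used by the lumped mRNA-inherited noise term, the per-gene minimum
#' mRNA floors, the division-fraction law (mean 0.42 in glucose, SD 0.05,
#' truncated to (0.05, 0.95)) and the division hysteresis threshold `k_flag`
#' (a cell that has divided cannot divide again until Clb2 rises above
#' `k_flag` > `k_ez`).
#'
#' @param k_tr,k_dm Translation and mRNA degradation rates.
#' @param m_min Named vector of per-gene mRNA floors.
#' @param div_mean,div_sd Division-fraction law.
#' @param k_flag Re-arming threshold (normalized concentration).
#' @param seed RNG seed.
#' @return A `noise_config` list.
#' @export
noise_config <- function(k_tr = 0.15, k_dm = 0.7,
                         m_min = c(cln2 = 5, cki = 5, clb5 = 5, clb2 = 5,
                                   pds1 = 5),
                         div_mean = division_fraction(100), div_sd = 0.05,
                         k_flag = 0.8, seed = 1L) {
  if (k_tr <= 0 || k_dm <= 0) abort("k_tr and k_dm must be positive")
  if (any(m_min < 0)) abort("mRNA floors must be non-negative")
  structure(list(k_tr = k_tr, k_dm = k_dm, m_min = m_min,
                 div_mean = div_mean, div_sd = div_sd, k_flag = k_flag,
                 seed = seed),
            class = "noise_config")
}

#' Elementary mass-action reaction network
#'
#' A minimal reaction-list container for exact stochastic simulation:
#' each reaction has a rate constant, a named vector of reactant
#' stoichiometries (propensity is mass-action in molecule counts) and a named
#' vector of state changes. Used for the small reference models against which
#' the Langevin layer is validated.
#'
#' @param species Character vector of species names.
#' @param reactions List of `list(rate, reactants, change)` entries.
#' @return A `reaction_network` object.
#' @export
reaction_network <- function(species, reactions) {
  for (r in reactions) {
    if (r$rate < 0) abort("reaction rates must be non-negative")
    if (length(setdiff(names(r$change), species)) > 0)
      abort("reaction changes reference unknown species")
  }
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' Gillespie stochastic simulation of a mass-action network
#'
#' Statistically exact simulation of a [reaction_network()] with integer
#' state, sampled on a regular output grid. Propensities are
#' `rate * prod(choose-like counts)` using simple `x^n` mass-action counting
#' (adequate for the zeroth/first/second-order reactions used here).
#'
#' @param net A [reaction_network()].
#' @param init Named integer vector of initial counts.
#' @param tend End time.
#' @param record_dt Output cadence.
#' @param seed Integer seed (uses R's RNG).
#' @return Tibble with `t` and one column per species.
#' @export
ssa_simulate <- function(net, init, tend, record_dt = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- init[net$species]
  t <- 0
  grid <- seq(0, tend, by = record_dt)
  out <- matrix(NA_real_, nrow = length(grid), ncol = length(x))
  gi <- 1L
  repeat {
    a <- vapply(net$reactions, function(r) {
      val <- r$rate
      if (length(r$reactants))
        for (nm in names(r$reactants)) val <- val * x[[nm]]^r$reactants[[nm]]
      val
    }, numeric(1))
    if (any(a < 0)) abort("negative propensity: model error")
    a0 <- sum(a)
    tau <- if (a0 > 0) stats::rexp(1, a0) else Inf
    while (gi <= length(grid) && grid[gi] <= t + tau) {
      out[gi, ] <- x
      gi <- gi + 1L
    }
    t <- t + tau
    if (t > tend || gi > length(grid) || !is.finite(t)) break
    j <- sample.int(length(a), 1, prob = a)
    ch <- net$reactions[[j]]$change
    x[names(ch)] <- x[names(ch)] + ch
  }
  colnames(out) <- net$species
  res <- as_tibble(as.data.frame(out[seq_len(gi - 1L), , drop = FALSE]))
  res$t <- grid[seq_len(gi - 1L)]
  dplyr::relocate(res, "t")
}

#' Stationary samples of a birth-death process (compiled helpers)
#'
#' `bd_cle_samples()` integrates the one-species chemical-Langevin equation
#' `dX = (A - BX)dt + ...` with optional lumped mRNA-inherited noise and
#' returns thinned post-burn-in samples; `bd_ssa_samples()` and
#' `bd2_ssa_samples()` are the exact one-stage and two-stage (mRNA + protein)
#' jump processes. The two-stage stationary protein noise obeys
#' `CV^2 = 1/<N> + (1/<m>) tau_m / (tau_m + tau_p)`.
#'
#' @param a,b Synthesis (molecules/min) and degradation (1/min) rates.
#' @param mbar,mmin,kdm mRNA-inherited noise parameters (`mbar = NULL` off).
#' @param dt,n_steps,burn,thin CLE sampling controls.
#' @param seed Integer seed.
#' @return Numeric vector of samples.
#' @export
bd_cle_samples <- function(a, b, mbar = NULL, mmin = 0, kdm = 0.7,
                           dt = 0.01, n_steps = 2e6, burn = 2e5, thin = 10,
                           seed = 1L) {
  bd_cle_cpp(a, b, if (is.null(mbar)) 0 else mbar, mmin, kdm, a / b, dt,
             as.integer(n_steps), as.integer(burn), as.integer(thin),
             as.integer(seed), !is.null(mbar))
}

#' @rdname bd_cle_samples
#' @param tend,sample_dt,burn_t SSA sampling controls (time units).
#' @export
bd_ssa_samples <- function(a, b, tend = 2e4, sample_dt = 1, burn_t = 200,
                           seed = 1L) {
  bd_ssa_cpp(a, b, tend, sample_dt, burn_t, as.integer(seed))
}

#' @rdname bd_cle_samples
#' @param ksm,ksp mRNA synthesis rate and per-mRNA translation rate.
#' @param kdp Protein degradation rate.
#' @export
bd2_ssa_samples <- function(ksm, kdm, ksp, kdp, tend = 2e4, sample_dt = 1,
                            burn_t = 200, seed = 1L) {
  bd2_ssa_cpp(ksm, kdm, ksp, kdp, tend, sample_dt, burn_t, as.integer(seed))
}
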