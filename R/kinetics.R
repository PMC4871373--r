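#' Soft-Heaviside (logistic) switching function
#'
#' `soft_heaviside()` is the sigmoidal rate law used by class-2 variables of a
#' standard component model: `H(x) = 1 / (1 + exp(-x))`. It replaces the hard
#' step function of piecewise-linear network models with a smooth,
#' ultrasensitive response whose steepness is set by the prefactor `sigma`
#' applied to its argument. `hard_heaviside()` is the step-function limit
#' (1 for `x >= 0`, else 0) used by the spindle progress variable.
#'
#' The implementation saturates to exactly 0 or 1 for very large `|x|` so that
#' it never overflows.
#'
#' @param x Numeric vector.
#' @return Numeric vector of values in `[0, 1]`.
#' @examples
#' soft_heaviside(0)      # 0.5
#' soft_heaviside(2)      # 1 / (1 + exp(-2))
#' @export
soft_heaviside <- function(x) {
  out <- ifelse(x > 500, 1, ifelse(x < -500, 0, 1 / (1 + exp(-x))))
  out
}

#' @rdname soft_heaviside
#' @export
hard_heaviside <- function(x) as.numeric(x >= 0)

#' Convert molecule numbers to nanomolar concentrations
#'
#' For a cell of volume `v` femtolitres, `[S] (nM) = N / (0.6 * v)`, where the
#' factor 0.6 is Avogadro's number times the fL-to-L and mol-to-nmol
#' conversions. `concentration_to_number()` is the inverse.
#'
#' @param n Molecule count(s).
#' @param v Cell volume in fL (strictly positive).
#' @return Concentration in nM (or molecule count for the inverse).
#' @examples
#' number_to_concentration(9, 1)    # 15 nM
#' concentration_to_number(15, 10)  # 90 molecules
#' @export
number_to_concentration <- function(n, v) {
  if (any(v <= 0)) abort("cell volume must be positive")
  n / (0.6 * v)
}

#' @rdname number_to_concentration
#' @param conc Concentration in nM.
#' @export
concentration_to_number <- function(conc, v) {
  if (any(v <= 0)) abort("cell volume must be positive")
  conc * 0.6 * v
}

#' One chemical-Langevin update of a class-1 variable
#'
#' Advances a molecule count `x` by one explicit Euler--Maruyama step of the
#' class-1 Langevin equation with a protein-noise term and (optionally) an
#' mRNA-inherited noise term:
#' \deqn{\Delta X = (A - BX)\Delta t + \sqrt{A + BX}\,\zeta_1\sqrt{\Delta t}
#'   + X\sqrt{2B}\sqrt{\frac{1}{\langle m\rangle + \langle m_{min}\rangle}
#'   \frac{B}{B + k_{dm}}}\,\zeta_2\sqrt{\Delta t}}
#' with independent standard-normal `zeta1`, `zeta2`. The result is clamped at
#' zero. With both noise amplitudes forced to zero (`zeta1 = zeta2 = 0`) the
#' update is exactly the deterministic Euler step.
#'
#' @param x Current molecule count (non-negative).
#' @param a Synthesis rate `A` (molecules/min, non-negative).
#' @param b Degradation rate constant `B` (1/min, non-negative).
#' @param dt Step size (min).
#' @param mbar Mean mRNA number feeding the mRNA-inherited term; `NULL`
#'   disables the term.
#' @param mmin Minimum mRNA floor added to `mbar`.
#' @param kdm mRNA degradation rate constant (1/min).
#' @param zeta1,zeta2 Standard-normal deviates; drawn internally if `NULL`.
#' @return Updated molecule count.
#' @export
langevin_step_class1 <- function(x, a, b, dt, mbar = NULL, mmin = 0,
                                 kdm = 0.7, zeta1 = NULL, zeta2 = NULL) {
  if (a < 0 || b < 0) abort("synthesis and degradation rates must be >= 0")
  if (is.null(zeta1)) zeta1 <- rnorm(1)
  if (is.null(zeta2)) zeta2 <- rnorm(1)
  dx <- (a - b * x) * dt + sqrt(max(0, a + b * x)) * zeta1 * sqrt(dt)
  if (!is.null(mbar)) {
    m_eff <- 1 / (mbar + mmin)
    dx <- dx + x * sqrt(2 * b) * sqrt(m_eff * b / (b + kdm)) * zeta2 * sqrt(dt)
  }
  max(0, x + dx)
}

#' Exponential growth law
#'
#' Cell volume grows exponentially, `V(t) = V0 exp(mu t)`, with specific growth
#' rate `mu = ln(2) / mdt` where `mdt` is the mass-doubling time of the
#' culture. Exactly one of `mu` and `mdt` must be given.
#'
#' @param v0 Initial volume (fL or normalized units).
#' @param mu Specific growth rate (1/min).
#' @param mdt Mass-doubling time (min).
#' @return A `growth_law` object (list with `v0`, `mu`, `mdt`).
#' @export
growth_law <- function(v0 = 1, mu = NULL, mdt = NULL) {
  if (is.null(mu) && is.null(mdt)) abort("supply mu or mdt")
  if (is.null(mu)) mu <- log(2) / mdt
  if (is.null(mdt)) mdt <- log(2) / mu
  if (v0 <= 0) abort("v0 must be positive")
  structure(list(v0 = v0, mu = mu, mdt = mdt), class = "growth_law")
}

#' Mother/daughter division fraction
#'
#' At division the daughter receives a fraction `f = 0.3364 exp(22.2 / T_d)`
#' of the dividing cell, where `T_d` is the mass-doubling time of the culture
#' in minutes; the mother keeps `1 - f`. In glucose (`T_d` = 100 min) the
#' mother:daughter ratio is 58:42, in galactose/raffinose (`T_d` = 150 min)
#' it is 61:39.
#'
#' @param td Mass-doubling time (min), positive.
#' @return Daughter volume fraction in (0, 1).
#' @examples
#' division_fraction(100) # ~0.42
#' @export
division_fraction <- function(td) {
  if (any(td <= 0)) abort("mass-doubling time must be positive")
  0.3364 * exp(22.2 / td)
}

#' Sample a stochastic division fraction
#'
#' Draws the daughter fraction from a normal law centred on `mean` with
#' standard deviation `sd`, truncated to (0.05, 0.95). With `sd = 0` the
#' deterministic fraction is returned.
#'
#' @param n Number of draws.
#' @param mean Mean fraction (default the glucose value 0.42...).
#' @param sd Standard deviation (default 0.05).
#' @return Numeric vector of fractions.
#' @export
sample_division_fraction <- function(n = 1, mean = division_fraction(100),
                                     sd = 0.05) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      f <- rnorm(1, mean, sd)
      if (f > 0.05 && f < 0.95) break
    }
    out[i] <- f
  }
  out
}
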