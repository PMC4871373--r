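#' Declarative specification of a standard component network
#'
#' A standard component model (SCM) partitions the species of a protein
#' regulatory network into three classes. Class-1 variables are protein totals
#' governed by pseudo-linear synthesis/degradation ODEs; class-2 variables are
#' protein activities relaxing towards `Y_T * H(sigma * W)` where `H` is the
#' soft-Heaviside function and `W` a weighted influence sum; class-3 variables
#' are free amounts of tightly bound complex partners, resolved algebraically
#' with max/min rules. `network_spec()` collects the species specifications
#' (plus a growth law) into a model that [scm_simulate()] can integrate.
#'
#' @param species A named list of `class1_spec`, `class2_spec` and
#'   `class3_spec` objects. Declaration order is the evaluation order of the
#'   algebraic (quasi-steady class-2 and class-3) pass.
#' @param growth A [growth_law()].
#' @param params Optional named numeric vector kept for reference (engines use
#'   it; the generic integrator reads rates from the specs themselves).
#' @param engine Identifier of a compiled fast path ("generic", "start",
#'   "cellcycle", "multip"); the generic R integrator works for any value.
#' @return A `network_spec` object.
#' @seealso [class1_spec()], [class2_spec()], [class3_spec()], [scm_simulate()]
#' @export
network_spec <- function(species, growth, params = NULL, engine = "generic") {
  stopifnot(is.list(species), inherits(growth, "growth_law"))
  nm <- vapply(species, function(s) s$name[1], character(1))
  names(species) <- nm
  structure(list(species = species, growth = growth, params = params,
                 engine = engine),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cls <- vapply(x$species, function(s) class(s)[1], character(1))
  cat("<network_spec> engine:", x$engine, "\n")
  cat("  species:", length(x$species),
      sprintf("(class1 %d, class2 %d, class3 %d)",
              sum(cls == "class1_spec"), sum(cls == "class2_spec"),
              sum(cls == "class3_spec")), "\n")
  cat("  growth: mu =", format(x$growth$mu), "per min (mdt",
      format(x$growth$mdt), "min)\n")
  invisible(x)
}

#' Rate term for a class-1 specification
#'
#' A rate term contributes `coef * prod(state[regulators]) * V^v_exp` to a
#' synthesis (`A`) or degradation (`B`) rate. All coefficients must be
#' non-negative; regulation signs are carried by whether a term sits in the
#' synthesis or degradation list.
#'
#' @param coef Non-negative rate coefficient.
#' @param regulators Character vector of species/derived names whose values
#'   multiply the term (may be empty).
#' @param v_exp Volume-dependence exponent (0, 1 or 2).
#' @export
rate_term <- function(coef, regulators = character(), v_exp = 0) {
  if (coef < 0) abort("rate coefficients must be non-negative")
  list(coef = coef, regulators = regulators, v_exp = v_exp)
}

#' Class-1 species: slow synthesis/degradation
#'
#' @param name Species name.
#' @param synthesis,degradation Lists of [rate_term()]s building the
#'   pseudo-linear rates `A` and `B` (the degradation rate multiplies the
#'   species value).
#' @param init Initial value (amount, non-negative).
#' @export
class1_spec <- function(name, synthesis = list(), degradation = list(),
                        init = 0) {
  structure(list(name = name, synthesis = synthesis, degradation = degradation,
                 init = init),
            class = "class1_spec")
}

#' Class-2 species: soft-Heaviside modification kinetics
#'
#' `dY/dt = gamma * (Y_T * H(sigma * W) - Y) - extra_deg * Y`, with influence
#' `W = w0 + sum(pos * state) - sum(neg * state)`, optionally divided by cell
#' volume (`per_volume`), and `Y` clamped to `[0, Y_T]`. With `qss = TRUE` the
#' variable is set algebraically to `Y_T * H(sigma * W)` each step.
#'
#' @param name Species name.
#' @param total Total amount: a number or the name of a (class-1) species.
#' @param gamma Relaxation rate constant (1/min).
#' @param sigma Steepness of the soft-Heaviside function.
#' @param w0 Signed background influence.
#' @param pos,neg Named numeric vectors of positive/negative influence weights
#'   (all weights themselves non-negative).
#' @param qss Quasi-steady-state flag.
#' @param per_volume Divide the influence sum by the current volume.
#' @param extra_deg Additional first-order loss applied to the active form.
#' @param init Initial value.
#' @export
class2_spec <- function(name, total, gamma, sigma, w0 = 0,
                        pos = numeric(), neg = numeric(), qss = FALSE,
                        per_volume = FALSE, extra_deg = 0, init = 0) {
  if (any(pos < 0) || any(neg < 0))
    abort("influence weights must be non-negative (signs are structural)")
  structure(list(name = name, total = total, gamma = gamma, sigma = sigma,
                 w0 = w0, pos = pos, neg = neg, qss = qss,
                 per_volume = per_volume, extra_deg = extra_deg, init = init),
            class = "class2_spec")
}

#' Class-3 species: algebraically resolved complexes
#'
#' Binding rules for rapidly equilibrating, strongly bound complexes:
#' * `"single"`: free `Y = max(0, Y_T - rho * I_T)`;
#' * `"shared"`: an inhibitor distributed between two partners in proportion
#'   to their totals;
#' * `"priority"`: the inhibitor binds partner 1 first, partner 2 with the
#'   remainder;
#' * `"min"`: complex abundance `min(a, b)` of its two operands;
#' * `"custom"`: arbitrary function `fn(state, v)` returning the value(s).
#'
#' @param name Name (character vector of length 2 for `"shared"`/`"priority"`,
#'   whose two free-partner amounts both become derived variables).
#' @param kind One of "single", "shared", "priority", "min", "custom".
#' @param operands Character vector of operand names; for "single" the pair
#'   `(Y_T, I_T)`, for "shared"/"priority" `(Y1_T, Y2_T, I_T)`, for "min" the
#'   two complexed partners.
#' @param rho Stoichiometric factor applied to the inhibitor ("single" only).
#' @param fn Function for `kind = "custom"`.
#' @export
class3_spec <- function(name, kind, operands = character(), rho = 1,
                        fn = NULL) {
  kind <- match.arg(kind, c("single", "shared", "priority", "min", "custom"))
  structure(list(name = name, kind = kind, operands = operands, rho = rho,
                 fn = fn),
            class = "class3_spec")
}

#' Net influence of the network on a class-2 variable
#'
#' `W = w0 + sum_k omega_k Y_k - sum_l omega_l Y_l` over the positive and
#' negative regulator sets, optionally divided by the volume.
#'
#' @param spec A [class2_spec()].
#' @param state Named numeric vector of current species values (including
#'   derived class-3 values).
#' @param v Current cell volume (used when `per_volume` is set).
#' @return The influence value `W`.
#' @export
influence <- function(spec, state, v = 1) {
  regs <- c(names(spec$pos), names(spec$neg))
  missing <- setdiff(regs, names(state))
  if (length(missing) > 0)
    abort(paste0("unknown regulator(s) in influence of '", spec$name, "': ",
                 paste(missing, collapse = ", ")))
  w <- spec$w0
  if (length(spec$pos)) w <- w + sum(spec$pos * state[names(spec$pos)])
  if (length(spec$neg)) w <- w - sum(spec$neg * state[names(spec$neg)])
  if (isTRUE(spec$per_volume)) w <- w / v
  unname(w)
}

#' Free amounts of class-3 complexes
#'
#' Resolves a [class3_spec()] against the current state. For the `"shared"`
#' rule with both partner totals zero the convention `(0, 0, max(0, I_T))` is
#' used.
#'
#' @inheritParams influence
#' @return Named numeric vector of the free amount(s).
#' @export
class3_free <- function(spec, state, v = 1) {
  op <- function(i) unname(state[[spec$operands[i]]])
  switch(spec$kind,
    single = setNames(max(0, op(1) - spec$rho * op(2)), spec$name[1]),
    shared = {
      y1t <- op(1); y2t <- op(2); it <- op(3)
      tot <- y1t + y2t
      if (tot <= 0) {
        out <- c(0, 0, max(0, it))
      } else {
        ex <- tot - it
        out <- c(max(0, y1t / tot * ex), max(0, y2t / tot * ex),
                 max(0, it - tot))
      }
      setNames(out, c(spec$name, paste0(spec$name[1], "_free_inhibitor"))[1:3])
    },
    priority = {
      y1t <- op(1); y2t <- op(2); it <- op(3)
      out <- c(max(0, y1t - it),
               min(max(0, y1t + y2t - it), y2t),
               max(0, it - y1t - y2t))
      setNames(out, c(spec$name, paste0(spec$name[1], "_free_inhibitor"))[1:3])
    },
    min = setNames(min(op(1), op(2)), spec$name[1]),
    custom = {
      val <- spec$fn(state, v)
      if (is.null(names(val))) names(val) <- spec$name
      val
    })
}

# evaluate one class-1 rate (A or B) from its term list
eval_rate <- function(terms, state, v) {
  if (length(terms) == 0) return(0)
  sum(vapply(terms, function(tm) {
    val <- tm$coef
    if (length(tm$regulators))
      val <- val * prod(state[tm$regulators])
    if (tm$v_exp != 0) val <- val * v^tm$v_exp
    val
  }, numeric(1)))
}

# refresh quasi-steady class-2 then class-3 values, in declaration order
refresh_algebraic <- function(net, state, v) {
  for (sp in net$species) {
    if (inherits(sp, "class2_spec") && isTRUE(sp$qss)) {
      tot <- if (is.character(sp$total)) state[[sp$total]] else sp$total
      state[sp$name] <- tot * soft_heaviside(sp$sigma * influence(sp, state, v))
    } else if (inherits(sp, "class3_spec")) {
      vals <- class3_free(sp, state, v)
      state[names(vals)[seq_along(sp$name)]] <- vals[seq_along(sp$name)]
    }
  }
  state
}

#' One explicit Euler step of a standard component network
#'
#' Advances all class-1 and dynamic class-2 variables by one explicit Euler
#' step, then recomputes quasi-steady class-2 and class-3 values from the
#' updated state (in declaration order), advances the volume by its exact
#' exponential factor, and applies the non-negativity / total clamps.
#'
#' @param net A [network_spec()].
#' @param state Named numeric vector (all dynamic and derived values).
#' @param v Current volume.
#' @param dt Step size (min), positive.
#' @param fixed_v Freeze the volume (for steady-state scans).
#' @return List with elements `state` and `v`.
#' @export
euler_step <- function(net, state, v, dt, fixed_v = FALSE) {
  if (dt <= 0) abort("dt must be positive")
  new <- state
  for (sp in net$species) {
    if (inherits(sp, "class1_spec")) {
      a <- eval_rate(sp$synthesis, state, v)
      b <- eval_rate(sp$degradation, state, v)
      d <- a - b * state[[sp$name]]
      if (!is.finite(d))
        abort(paste0("non-finite derivative for '", sp$name, "'"))
      new[sp$name] <- max(0, state[[sp$name]] + d * dt)
    } else if (inherits(sp, "class2_spec") && !isTRUE(sp$qss)) {
      tot <- if (is.character(sp$total)) state[[sp$total]] else sp$total
      w <- influence(sp, state, v)
      d <- sp$gamma * (tot * soft_heaviside(sp$sigma * w) - state[[sp$name]]) -
        sp$extra_deg * state[[sp$name]]
      if (!is.finite(d))
        abort(paste0("non-finite derivative for '", sp$name, "'"))
      new[sp$name] <- state[[sp$name]] + d * dt
    }
  }
  if (!fixed_v) v <- v * exp(net$growth$mu * dt)
  # clamp class-2 to [0, total] against the updated totals
  for (sp in net$species) {
    if (inherits(sp, "class2_spec")) {
      tot <- if (is.character(sp$total)) new[[sp$total]] else sp$total
      new[sp$name] <- min(max(0, new[[sp$name]]), tot)
    }
  }
  new <- refresh_algebraic(net, new, v)
  list(state = new, v = v)
}

#' Integrate a standard component network (generic reference integrator)
#'
#' Fixed-step explicit Euler integration of any [network_spec()]. This is the
#' slow, fully general path; the bundled yeast models dispatch to compiled
#' equivalents through their own simulate functions, and this integrator
#' serves as their independent cross-check.
#'
#' @param net A [network_spec()].
#' @param init Named numeric vector of initial values. Missing dynamic species
#'   default to their spec `init`; derived values are computed.
#' @param tend End time (min).
#' @param dt Step size (min), default 0.01.
#' @param record_dt Output cadence (min), default 0.1.
#' @param v0 Initial volume; defaults to the growth law's.
#' @param fixed_v Freeze the volume.
#' @return A tibble: `t`, `v`, then one column per species/derived value.
#' @export
scm_simulate <- function(net, init = NULL, tend, dt = 0.01, record_dt = 0.1,
                         v0 = NULL, fixed_v = FALSE) {
  v <- if (is.null(v0)) net$growth$v0 else v0
  state <- scm_initial_state(net, init, v)
  nsteps <- ceiling(tend / dt)
  rec_every <- max(1L, round(record_dt / dt))
  rows <- vector("list", nsteps %/% rec_every + 1L)
  irow <- 1L
  t <- 0
  for (step in 0:nsteps) {
    if (step %% rec_every == 0) {
      rows[[irow]] <- c(t = t, v = v, state)
      irow <- irow + 1L
    }
    if (step == nsteps) break
    res <- euler_step(net, state, v, dt, fixed_v = fixed_v)
    state <- res$state
    v <- res$v
    t <- t + dt
  }
  as_tibble(as.data.frame(do.call(rbind, rows[seq_len(irow - 1L)])))
}

#' @rdname scm_simulate
#' @param v Volume at which derived values are computed.
#' @export
scm_initial_state <- function(net, init = NULL, v = NULL) {
  if (is.null(v)) v <- net$growth$v0
  state <- numeric()
  for (sp in net$species) {
    if (inherits(sp, "class3_spec")) {
      for (nm in sp$name) state[nm] <- 0
      if (sp$kind %in% c("shared", "priority"))
        state[paste0(sp$name[1], "_free_inhibitor")] <- 0
    } else {
      state[sp$name] <- sp$init
    }
  }
  if (!is.null(init)) state[names(init)] <- init
  # two passes so quasi-steady activities see the class-3 values computed in
  # the first pass (their declaration precedes the complex chain)
  state <- refresh_algebraic(net, state, v)
  refresh_algebraic(net, state, v)
}
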