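#' Uniform kinetic rate parameters
#'
#' One global parameter set applied to every reaction (the prototype has no
#' per-reaction values; use `overrides` in the injectors for per-reaction
#' rate constants). All constants are strictly positive; units are
#' dimensionless by declaration.
#'
#' @param k_f Mass-action rate constant (per time, per concentration to the
#'   reaction order minus one). Default 1.
#' @param v_max Michaelis-Menten limiting rate (concentration/time). Default 1.
#' @param k_m Michaelis constant (concentration). Default 1.
#' @return An object of class `"rate_params"`.
#' @export
rate_params <- function(k_f = 1.0, v_max = 1.0, k_m = 1.0) {
  stopifnot(k_f > 0, v_max > 0, k_m > 0)
  structure(list(k_f = k_f, v_max = v_max, k_m = k_m), class = "rate_params")
}

.fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

# k_f * A^2 * B style product over reactants; empty product -> bare constant.
.mass_action_expression <- function(reaction, k_f) {
  fwd <- .stoich_product(reaction$reactants)
  if (!reaction$reversible) {
    expr <- if (is.null(fwd)) "k_f" else paste("k_f", fwd, sep = " * ")
    return(expr)
  }
  rev <- .stoich_product(reaction$products)
  fwd <- fwd %||% "1"
  rev <- rev %||% "1"
  sprintf("k_f * (%s - %s)", fwd, rev)
}

.stoich_product <- function(refs) {
  if (!length(refs)) return(NULL)
  terms <- vapply(refs, function(p) {
    if (p$stoichiometry == 1) p$species_id
    else paste0(p$species_id, "^", .fmt_num(p$stoichiometry))
  }, character(1))
  paste(terms, collapse = " * ")
}

#' Inject mass-action kinetic laws
#'
#' Every reaction receives the law `v = k_f * prod_i [R_i]^s_i` over its
#' reactants; a reaction with no reactants becomes a constant source
#' `v = k_f`. Reactions flagged reversible receive the net law
#' `v = k_f * (prod reactants - prod products)`, so a symmetric isomerism
#' relaxes to detailed balance. Modifiers are ignored. Reactions that
#' already carry a law are skipped with a warning unless `overwrite = TRUE`.
#'
#' @param model A [pathway_model()].
#' @param params A [rate_params()].
#' @param overwrite Replace existing kinetic laws? Default `FALSE`.
#' @param overrides Optional named numeric vector of per-reaction `k_f`
#'   values keyed by reaction id.
#' @return The model with kinetic laws attached.
#' @export
add_mass_action <- function(model, params = rate_params(), overwrite = FALSE,
                            overrides = NULL) {
  stopifnot(inherits(model, "pathway_model"), inherits(params, "rate_params"))
  skipped <- character()
  model$reactions <- lapply(model$reactions, function(r) {
    if (!is.null(r$kinetic_law) && !overwrite) {
      skipped <<- c(skipped, r$reaction_id)
      return(r)
    }
    k_f <- if (!is.null(overrides) && r$reaction_id %in% names(overrides)) {
      overrides[[r$reaction_id]]
    } else params$k_f
    r$kinetic_law <- kinetic_law("mass_action",
                                 .mass_action_expression(r, k_f),
                                 list(k_f = k_f))
    r
  })
  if (length(skipped)) {
    warning("kept existing kinetic law on: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  }
  model
}

#' Inject Michaelis-Menten kinetic laws
#'
#' Every reaction with at least one reactant receives
#' `v = v_max * S / (k_m + S)` with `S` the first listed reactant (the
#' substrate-first convention; the enzyme, when modelled, is a modifier and
#' does not enter the rate). Reactions without reactants are skipped; their
#' ids are attached as attribute `"skipped"`.
#'
#' @inheritParams add_mass_action
#' @return The model with kinetic laws attached; attribute `"skipped"`
#'   lists reactions left without a law.
#' @export
add_michaelis_menten <- function(model, params = rate_params(), overwrite = FALSE) {
  stopifnot(inherits(model, "pathway_model"), inherits(params, "rate_params"))
  skipped <- character()
  kept <- character()
  model$reactions <- lapply(model$reactions, function(r) {
    if (!length(r$reactants)) {
      skipped <<- c(skipped, r$reaction_id)
      return(r)
    }
    if (!is.null(r$kinetic_law) && !overwrite) {
      kept <<- c(kept, r$reaction_id)
      return(r)
    }
    s <- r$reactants[[1L]]$species_id
    r$kinetic_law <- kinetic_law(
      "michaelis_menten",
      sprintf("v_max * %s / (k_m + %s)", s, s),
      list(v_max = params$v_max, k_m = params$k_m)
    )
    r
  })
  if (length(kept)) {
    warning("kept existing kinetic law on: ", paste(kept, collapse = ", "),
            call. = FALSE)
  }
  attr(model, "skipped") <- skipped
  model
}

#' Deterministic sanity simulation of a parameterized model
#'
#' Integrates `d[X]/dt = sum_r (s_out - s_in) * v_r` with the classical
#' fourth-order Runge-Kutta scheme on a fixed step grid (via
#' [deSolve::ode()] with `method = "rk4"`). Every reaction must carry a
#' kinetic law; species without an initial amount start at 1. This is a
#' validation harness for injected laws, not a production solver.
#'
#' @param model A [pathway_model()] whose reactions all have kinetic laws.
#' @param t_end End time (dimensionless). Default 10.
#' @param dt Fixed step size. Default 0.01.
#' @return A data frame: column `time` plus one concentration column per
#'   species.
#' @export
simulate_kinetics <- function(model, t_end = 10, dt = 0.01) {
  stopifnot(inherits(model, "pathway_model"), t_end > 0, dt > 0)
  no_law <- vapply(model$reactions, function(r) is.null(r$kinetic_law), logical(1))
  if (any(no_law)) {
    stop("reaction(s) without kinetic law: ",
         paste(vapply(model$reactions[no_law], `[[`, character(1), "reaction_id"),
               collapse = ", "), call. = FALSE)
  }
  sp_ids <- names(model$species)
  y0 <- vapply(model$species, function(s) {
    if (is.na(s$initial_amount)) 1 else s$initial_amount
  }, numeric(1))
  names(y0) <- sp_ids

  # net stoichiometry matrix (species x reactions) and compiled rate closures
  nu <- matrix(0, nrow = length(sp_ids), ncol = length(model$reactions),
               dimnames = list(sp_ids, NULL))
  rates <- vector("list", length(model$reactions))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (p in r$reactants) nu[p$species_id, j] <- nu[p$species_id, j] - p$stoichiometry
    for (p in r$products) nu[p$species_id, j] <- nu[p$species_id, j] + p$stoichiometry
    env <- new.env(parent = baseenv())
    for (nm in names(r$kinetic_law$parameters)) {
      assign(nm, r$kinetic_law$parameters[[nm]], envir = env)
    }
    rates[[j]] <- list(expr = parse(text = r$kinetic_law$expression)[[1]], env = env)
  }

  deriv <- function(t, y, parms) {
    v <- vapply(rates, function(rt) {
      for (nm in names(y)) assign(nm, y[[nm]], envir = rt$env)
      eval(rt$expr, envir = rt$env)
    }, numeric(1))
    list(as.numeric(nu %*% v))
  }

  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  out <- as.data.frame(sol)
  if (any(!is.finite(as.matrix(out)))) {
    bad <- which(!stats::complete.cases(is.finite(as.matrix(out[-1]))))[1]
    first_bad <- out$time[which(rowSums(!is.finite(as.matrix(out[-1]))) > 0)[1]]
    stop("integration error: non-finite state at t = ", first_bad, call. = FALSE)
  }
  out
}
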