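#' Define an ODE model
#'
#' Builds the single-cell-type model structure: states with their right-hand
#' sides \eqn{\dot x = f(x, u, p)}, observation functions \eqn{g_i(x, p)},
#' inputs \eqn{u(t)}, parameters and initial conditions. The model is the
#' template that [replicate_model()] copies across cell types.
#'
#' All expressions may be given as one-sided formulas (`~ -p * x`), character
#' strings (`"-p * x"`), or quoted calls. Every symbol appearing in an
#' expression must resolve to a state, an input, a parameter, the time symbol
#' `t`, or a condition constant declared in `condition_vars`.
#'
#' Parameters flagged log-scale (the default) are estimated as log10 of the
#' natural value, which keeps them strictly positive; observation-scale
#' offsets can opt out via `log_scale`.
#'
#' @param states character vector of state names.
#' @param odes named list of expressions, one per state, giving \eqn{f}.
#' @param observables named list of expressions \eqn{g_i(x, p)}.
#' @param parameters character vector of parameter names, or a named numeric
#'   vector of default values on the estimation scale (log10 for log-scale
#'   parameters).
#' @param initials named list (one entry per state) of expressions of
#'   parameters, or numeric constants.
#' @param inputs named list of expressions in `t` and condition constants,
#'   e.g. `list(L = ~ dose)`. May be empty.
#' @param log_scale logical vector (recycled or named) marking which
#'   parameters are estimated on log10 scale. Default: all of them.
#' @param condition_vars character vector of per-condition constant names
#'   that input expressions may reference (e.g. `"dose"`).
#'
#' @return An object of class `ode_model`.
#' @examples
#' decay <- ode_model(
#'   states = "x",
#'   odes = list(x = ~ -p * x),
#'   observables = list(x_obs = ~x),
#'   parameters = c(p = -1),
#'   initials = list(x = 1)
#' )
#' @export
ode_model <- function(states, odes, observables, parameters,
                      initials, inputs = list(), log_scale = TRUE,
                      condition_vars = character()) {
  states <- as.character(states)
  stopifnot(length(states) >= 1L, !anyDuplicated(states))

  if (is.numeric(parameters)) {
    par_names <- names(parameters)
    par_default <- unname(parameters)
  } else {
    par_names <- as.character(parameters)
    par_default <- rep(0, length(par_names))
  }
  if (is.null(par_names) || anyDuplicated(par_names) || any(par_names == "")) {
    stop("`parameters` must be uniquely named", call. = FALSE)
  }
  if (is.null(names(log_scale))) {
    log_scale <- rep_len(log_scale, length(par_names))
    names(log_scale) <- par_names
  } else {
    ls <- rep(TRUE, length(par_names))
    names(ls) <- par_names
    ls[names(log_scale)] <- log_scale
    log_scale <- ls
  }

  odes <- as_expr_list(odes, states, "odes")
  observables <- as_expr_list(observables, NULL, "observables")
  initials <- as_expr_list(initials, states, "initials")
  inputs <- as_expr_list(inputs, NULL, "inputs")

  known <- c(states, par_names, names(inputs), "t", condition_vars)
  for (set in list(odes, observables, initials)) {
    for (nm in names(set)) {
      syms <- all.vars(set[[nm]])
      bad <- setdiff(syms, known)
      if (length(bad)) {
        stop(sprintf("unresolved symbol(s) %s in expression for '%s'",
                     paste0("'", bad, "'", collapse = ", "), nm),
             call. = FALSE)
      }
    }
  }
  for (nm in names(inputs)) {
    bad <- setdiff(all.vars(inputs[[nm]]), c("t", condition_vars))
    if (length(bad)) {
      stop(sprintf("input '%s' may only depend on t and condition constants; found %s",
                   nm, paste0("'", bad, "'", collapse = ", ")), call. = FALSE)
    }
  }

  m <- structure(
    list(
      states = states,
      odes = odes,
      observables = observables,
      parameters = par_names,
      default = stats::setNames(par_default, par_names),
      log_scale = log_scale,
      initials = initials,
      inputs = inputs,
      condition_vars = condition_vars
    ),
    class = "ode_model"
  )
  m$derivs <- compile_model_derivs(m)
  m$fast_rhs <- build_fast_rhs(m)
  m
}

# normalize formula / character / call / numeric entries to language objects
as_expr_list <- function(x, required_names, what) {
  if (length(x) == 0L) return(stats::setNames(list(), character()))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop(sprintf("`%s` entries must be named", what), call. = FALSE)
  }
  out <- lapply(x, function(e) {
    if (inherits(e, "formula")) e[[length(e)]]
    else if (is.character(e)) str2lang(e)
    else if (is.numeric(e)) e
    else if (is.language(e)) e
    else stop(sprintf("cannot interpret an entry of `%s` as an expression", what),
              call. = FALSE)
  })
  if (!is.null(required_names)) {
    missing <- setdiff(required_names, names(out))
    if (length(missing)) {
      stop(sprintf("`%s` missing entries for: %s", what,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    out <- out[required_names]
  }
  out
}

# symbolic derivative, with numeric constants handled
d_expr <- function(expr, name) {
  if (is.numeric(expr)) return(0)
  stats::D(expr, name)
}

# Precompute all symbolic derivatives needed for forward sensitivities:
# df/dx, df/dp, dg/dx, dg/dp, dx0/dp (natural-scale parameter symbols).
compile_model_derivs <- function(m) {
  st <- m$states
  pn <- m$parameters
  list(
    dfdx = lapply(m$odes, function(e) lapply(stats::setNames(st, st), d_expr, expr = e)),
    dfdp = lapply(m$odes, function(e) lapply(stats::setNames(pn, pn), d_expr, expr = e)),
    dgdx = lapply(m$observables, function(e) lapply(stats::setNames(st, st), d_expr, expr = e)),
    dgdp = lapply(m$observables, function(e) lapply(stats::setNames(pn, pn), d_expr, expr = e)),
    dx0dp = lapply(m$initials, function(e) lapply(stats::setNames(pn, pn), d_expr, expr = e))
  )
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", length(x$states), " state(s), ",
      length(x$parameters), " parameter(s), ",
      length(x$observables), " observable(s)\n", sep = "")
  for (s in x$states) {
    cat("  d", s, "/dt = ", deparse1(x$odes[[s]]), "\n", sep = "")
  }
  for (o in names(x$observables)) {
    cat("  ", o, " = ", deparse1(x$observables[[o]]), "\n", sep = "")
  }
  invisible(x)
}

# natural-scale parameter values from estimation-scale vector
natural_params <- function(model, est) {
  v <- est[model$parameters]
  ifelse(model$log_scale[model$parameters], 10^v, v)
}

# chain-rule factor d(natural)/d(estimation scale): ln(10)*p for log10 pars
dnatural_dest <- function(model, p_nat) {
  ifelse(model$log_scale[model$parameters], log(10) * p_nat, 1)
}
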