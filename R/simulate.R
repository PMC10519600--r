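#' Integrate one cell type's ODE system with forward sensitivities
#'
#' Solves the augmented system \eqn{\dot x = f(x, u, p)},
#' \eqn{\dot S = (\partial f/\partial x) S + \partial f/\partial \theta} with
#' \eqn{S(0) = \partial x(0)/\partial \theta}, where \eqn{\theta} are the
#' model's parameters on the estimation scale (log10 for log-scale
#' parameters; chain rule \eqn{\partial/\partial \log_{10} p = \ln(10)\, p\,
#' \partial/\partial p}). The Jacobians \eqn{\partial f/\partial x} and
#' \eqn{\partial f/\partial p} are derived symbolically when the model is
#' built and assembled into a generated right-hand-side function.
#'
#' @param mcm a [replicate_model()] object.
#' @param theta flat parameter vector.
#' @param cell_type cell type to simulate.
#' @param times ascending time grid starting at 0.
#' @param condition named list of condition constants (for dose-response
#'   designs); empty for models without condition variables.
#' @param rtol,atol integrator tolerances. Defaults are two orders of
#'   magnitude tighter than the optimizer's termination tolerance.
#' @return list with `times`, state matrix `x` (times x states) and
#'   sensitivity array `S` (times x states x model parameters, estimation
#'   scale).
#' @export
integrate_with_sensitivities <- function(mcm, theta, cell_type, times,
                                         condition = list(),
                                         rtol = 1e-8, atol = 1e-10) {
  check_theta(mcm, theta)
  model <- mcm$model
  est <- expand_parameters(mcm, theta, cell_type)
  p_nat <- natural_params(model, est)
  chain <- dnatural_dest(model, p_nat)
  ns <- length(model$states)
  np <- length(model$parameters)

  if (is.unsorted(times, strictly = FALSE)) {
    stop("`times` must be sorted ascending", call. = FALSE)
  }
  grid <- times
  prepended <- FALSE
  if (grid[1] > 0) {
    grid <- c(0, grid)
    prepended <- TRUE
  } else if (grid[1] < 0) {
    stop("`times` must start at 0 or later", call. = FALSE)
  }

  env <- list2env(c(as.list(p_nat), condition, list(.chain = chain)),
                  parent = baseenv())

  # initial conditions and their parameter sensitivities
  x0 <- vapply(model$states, function(s) eval(model$initials[[s]], env), numeric(1))
  S0 <- matrix(0, ns, np)
  for (k in seq_len(ns)) {
    dd <- model$derivs$dx0dp[[model$states[k]]]
    for (i in seq_len(np)) {
      if (!is_zero_expr(dd[[i]])) {
        S0[k, i] <- eval(dd[[i]], env) * chain[i]
      }
    }
  }

  rhs <- model$fast_rhs
  y0 <- c(x0, as.vector(S0))
  sol <- deSolve::lsoda(y0, grid, rhs, parms = env, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(grid)) {
    stop(sprintf(
      "ODE integration failed for cell type %d at theta = (%s)",
      cell_type, paste(signif(theta, 6), collapse = ", ")), call. = FALSE)
  }
  sol <- unclass(sol)[, -1, drop = FALSE]
  if (prepended) sol <- sol[-1, , drop = FALSE]
  nt <- nrow(sol)
  x <- sol[, seq_len(ns), drop = FALSE]
  colnames(x) <- model$states
  S <- array(sol[, -seq_len(ns)], dim = c(nt, ns, np),
             dimnames = list(NULL, model$states, model$parameters))
  list(times = times, x = x, S = S, est = est, p_nat = p_nat, chain = chain,
       env = env)
}

is_zero_expr <- function(e) is.numeric(e) && length(e) == 1L && e == 0

# Generate the augmented right-hand-side function for deSolve from the
# model's symbolic derivatives. Zero entries of df/dx and df/dp are dropped
# at generation time; `parms` is an environment carrying natural-scale
# parameters, condition constants and the log-scale chain factors, in which
# the generated body is evaluated directly.
build_fast_rhs <- function(model) {
  ns <- length(model$states)
  np <- length(model$parameters)
  lines <- "{"
  for (nm in names(model$inputs)) {
    lines <- c(lines, sprintf("  %s <- %s", nm, deparse1(model$inputs[[nm]])))
  }
  for (k in seq_len(ns)) {
    lines <- c(lines, sprintf("  %s <- y[%dL]", model$states[k], k))
  }
  fparts <- vapply(model$states, function(s)
    deparse1(model$odes[[s]]), character(1))
  lines <- c(lines, sprintf("  f <- c(%s)", paste(fparts, collapse = ", ")))
  lines <- c(lines, sprintf("  S <- matrix(y[-seq_len(%dL)], %dL, %dL)",
                            ns, ns, np))
  lines <- c(lines, sprintf("  A <- matrix(0, %dL, %dL)", ns, ns),
             sprintf("  B <- matrix(0, %dL, %dL)", ns, np))
  for (k in seq_len(ns)) {
    dfx <- model$derivs$dfdx[[model$states[k]]]
    dfp <- model$derivs$dfdp[[model$states[k]]]
    for (l in seq_len(ns)) {
      if (!is_zero_expr(dfx[[l]])) {
        lines <- c(lines, sprintf("  A[%dL, %dL] <- %s", k, l,
                                  deparse1(dfx[[l]])))
      }
    }
    for (i in seq_len(np)) {
      if (!is_zero_expr(dfp[[i]])) {
        lines <- c(lines, sprintf("  B[%dL, %dL] <- (%s) * .chain[%dL]",
                                  k, i, deparse1(dfp[[i]]), i))
      }
    }
  }
  lines <- c(lines, "  list(c(f, A %*% S + B))", "}")
  expr <- parse(text = paste(lines, collapse = "\n"))[[1]]
  function(t, y, parms) {
    assign("t", t, envir = parms)
    assign("y", y, envir = parms)
    eval(expr, parms)
  }
}

# Observable values and their sensitivities w.r.t. the model's own
# estimation-scale parameters, vectorized over the trajectory's time grid.
eval_observables <- function(mcm, traj, observables, condition = list()) {
  model <- mcm$model
  np <- length(model$parameters)
  nt <- length(traj$times)
  env <- new.env(parent = traj$env)
  assign("t", traj$times, envir = env)
  for (nm in names(model$inputs)) {
    assign(nm, rep_len(eval(model$inputs[[nm]], env), nt), envir = env)
  }
  for (k in seq_along(model$states)) {
    assign(model$states[k], traj$x[, k], envir = env)
  }

  out <- list()
  for (ob in unique(observables)) {
    g <- model$observables[[ob]]
    if (is.null(g)) stop("observable not defined in model: ", ob, call. = FALSE)
    dgx <- model$derivs$dgdx[[ob]]
    dgp <- model$derivs$dgdp[[ob]]
    y <- rep_len(eval(g, env), nt)
    dy <- matrix(0, nt, np, dimnames = list(NULL, model$parameters))
    for (i in seq_len(np)) {
      acc <- if (is_zero_expr(dgp[[i]])) numeric(nt) else {
        rep_len(eval(dgp[[i]], env), nt) * traj$chain[i]
      }
      for (k in seq_along(model$states)) {
        if (!is_zero_expr(dgx[[k]])) {
          acc <- acc + rep_len(eval(dgx[[k]], env), nt) * traj$S[, k, i]
        }
      }
      dy[, i] <- acc
    }
    out[[ob]] <- list(y = y, dy = dy)
  }
  out
}

# map a (rows x model-parameters) sensitivity matrix into the global theta
# columns for a given cell type: specific parameters contribute to both the
# base column and (off reference) the fold-change column.
map_to_theta <- function(mcm, dy, cell_type) {
  J <- matrix(0, nrow(dy), length(mcm$theta_names),
              dimnames = list(NULL, mcm$theta_names))
  J[, names(mcm$base_idx)] <- dy[, mcm$model$parameters, drop = FALSE]
  if (cell_type != mcm$reference) {
    for (pn in mcm$specific) {
      J[, mcm$r_index[pn, cell_type]] <- dy[, pn]
    }
  }
  J
}

#' Data residuals and their Jacobian
#'
#' The residual for data row \eqn{(i, t)} is
#' \eqn{(y^*_{i,t} - y_i(t, \theta)) / (\sqrt{2}\,\sigma_{i,t})}, so the sum
#' of squared residuals equals the half-weighted sum of squares
#' \eqn{\chi^2 = \sum (y^* - y)^2 / (2\sigma^2)} exactly. Jacobian rows are
#' assembled from the forward observable sensitivities by the chain rule.
#'
#' @param mcm a [replicate_model()] object.
#' @param theta flat parameter vector.
#' @param data an experiment table (see [read_experiment_table()]): columns
#'   `time`, `observable`, `value`, `sigma`, `cell_type`, optional
#'   `condition`.
#' @param conditions named list of per-condition constant lists; only needed
#'   for models with condition variables.
#' @param rtol,atol integrator tolerances.
#' @return list with `res` (residual vector), `J` (rows x theta Jacobian),
#'   `tag = "data"` and the row metadata.
#' @export
data_residuals <- function(mcm, theta, data, conditions = list(),
                           rtol = 1e-8, atol = 1e-10) {
  data <- validate_experiment_table(data, mcm)
  nr <- nrow(data)
  yhat <- numeric(nr)
  J <- matrix(0, nr, length(mcm$theta_names),
              dimnames = list(NULL, mcm$theta_names))

  key <- paste(data$cell_type, data$condition, sep = "\r")
  for (kk in unique(key)) {
    rows <- which(key == kk)
    ct <- data$cell_type[rows[1]]
    cond_id <- data$condition[rows[1]]
    cond <- conditions[[cond_id]] %||% list()
    tt <- sort(unique(data$time[rows]))
    traj <- integrate_with_sensitivities(mcm, theta, ct, tt, cond,
                                         rtol = rtol, atol = atol)
    obs <- eval_observables(mcm, traj, data$observable[rows], cond)
    for (ob in unique(data$observable[rows])) {
      orow <- rows[data$observable[rows] == ob]
      it <- match(data$time[orow], tt)
      yhat[orow] <- obs[[ob]]$y[it]
      J[orow, ] <- map_to_theta(mcm, obs[[ob]]$dy[it, , drop = FALSE], ct)
    }
  }
  w <- sqrt(2) * data$sigma
  res <- (data$value - yhat) / w
  J <- J / -w
  list(res = res, J = J, tag = "data", yhat = yhat, data = data)
}

#' Chi-square goodness of fit
#'
#' @inheritParams data_residuals
#' @return the scalar \eqn{\chi^2 = \sum (y^* - y)^2 / (2\sigma^2)}.
#' @export
chi_square <- function(mcm, theta, data, conditions = list(), ...) {
  sum(data_residuals(mcm, theta, data, conditions, ...)$res^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
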