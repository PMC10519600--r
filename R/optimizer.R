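#' Optimizer options
#'
#' All tunables of the adapted trust-region least-squares loop in one record.
#'
#' @param max_iter maximum accepted iterations.
#' @param gtol tolerance on directional derivatives of the objective for the
#'   optimality criteria.
#' @param xtol relative step-norm threshold below which iteration stops.
#' @param ftol relative objective-decrease threshold; iteration stops after
#'   `stall_iter` consecutive accepted steps improving less than this.
#' @param stall_iter see `ftol`.
#' @param mu0 initial Levenberg-Marquardt damping.
#' @param mu_max damping value at which the line search gives up.
#' @param accept_ratio minimum ratio of actual to predicted objective
#'   reduction for a step to be accepted.
#' @param rtol,atol ODE integrator tolerances (kept at least two orders
#'   tighter than `gtol`).
#' @param merge_rule how sensitivities of a dominated on-manifold cluster are
#'   combined: `"mean"` (default), `"max"` (maximum absolute value, kept for
#'   comparison), or `"zero"` (the naive rule that freezes the coordinates
#'   and cannot move a nonzero cluster to the origin; retained to
#'   demonstrate why the mean rule is needed).
#' @param trace record a per-iteration log in the fit result.
#' @return a list of class `fit_control`.
#' @export
fit_control <- function(max_iter = 500L, gtol = 1e-6, xtol = 1e-10,
                        ftol = 1e-10, stall_iter = 3L,
                        mu0 = 1e-3, mu_max = 1e12, accept_ratio = 1e-4,
                        rtol = 1e-8, atol = 1e-10,
                        merge_rule = c("mean", "max", "zero"),
                        trace = FALSE) {
  merge_rule <- match.arg(merge_rule)
  structure(as.list(environment()), class = "fit_control")
}

# Affine reduction theta_full = A %*% theta_red + b implementing fixed base
# parameters and tied / zeroed fold-change coordinates (constrained refits).
build_reduction <- function(mcm, fixed = NULL, ties = NULL) {
  full <- mcm$theta_names
  nb <- length(mcm$base_idx)
  b <- stats::setNames(numeric(length(full)), full)
  col_of <- stats::setNames(integer(length(full)), full) # 0 = no free column
  red_names <- character()

  add_col <- function(nm) {
    red_names[[length(red_names) + 1L]] <<- nm
    length(red_names)
  }
  for (nm in full[seq_len(nb)]) {
    if (!is.null(fixed) && nm %in% names(fixed)) {
      b[nm] <- fixed[[nm]]
    } else {
      col_of[nm] <- add_col(nm)
    }
  }
  r_names <- full[-seq_len(nb)]
  if (is.null(ties)) {
    for (nm in r_names) col_of[nm] <- add_col(nm)
  } else {
    if (!all(r_names %in% names(ties))) {
      stop("`ties` must cover every fold-change coordinate", call. = FALSE)
    }
    group_col <- list()
    for (nm in r_names) {
      g <- as.character(ties[[nm]])
      if (g == "0") next # fixed at zero
      if (is.null(group_col[[g]])) group_col[[g]] <- add_col(paste0("tie_", g))
      col_of[nm] <- group_col[[g]]
    }
  }
  A <- matrix(0, length(full), length(red_names),
              dimnames = list(full, red_names))
  for (nm in full) if (col_of[nm] > 0L) A[nm, col_of[nm]] <- 1
  list(A = A, b = b, col_of = col_of, red_names = red_names)
}

reduce_start <- function(red, start) {
  out <- stats::setNames(numeric(length(red$red_names)), red$red_names)
  cnt <- numeric(length(out))
  for (nm in names(red$col_of)) {
    cl <- red$col_of[nm]
    if (cl > 0L) {
      out[cl] <- out[cl] + start[nm]
      cnt[cl] <- cnt[cl] + 1
    }
  }
  out / pmax(cnt, 1)
}

#' Truncate an optimization step at sign changes
#'
#' Computes the largest scalar fraction `t` in (0, 1] of the proposed step
#' such that no penalized fold-change difference \eqn{r_i^{(j)} - r_i^{(k)}}
#' (including differences to the reference, i.e. the fold changes
#' themselves) changes sign along the scaled step. If a sign change would
#' occur, the step lands exactly on the first crossing, i.e. on the
#' \eqn{\Delta = 0} manifold, where the optimality criterion is evaluated
#' before any further step. The whole step vector is scaled by one scalar;
#' coordinates are never clipped individually, so several coincident
#' crossings land on their manifolds simultaneously.
#'
#' @param mcm a [replicate_model()] object.
#' @param theta current flat parameter vector.
#' @param step proposed step in the same coordinates.
#' @param spec a [penalty_spec()]; its pair list defines which differences
#'   are protected.
#' @return list with `t` (scalar factor), `step` (truncated step), and
#'   `crossings` (row indices of the pair table that land on their manifold).
#' @export
truncate_step <- function(mcm, theta, step, spec) {
  pairs <- pair_terms(mcm, spec)
  delta <- pair_deltas(mcm, theta, pairs)
  dstep <- pair_deltas(mcm, stats::setNames(step, mcm$theta_names), pairs)
  tfac <- 1
  tcross <- rep(Inf, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (abs(delta[i]) < spec$epsilon) next   # already on its manifold
    if (dstep[i] == 0) next
    endv <- delta[i] + dstep[i]
    if (sign(endv) != sign(delta[i])) {
      tcross[i] <- -delta[i] / dstep[i]
    }
  }
  if (any(is.finite(tcross))) tfac <- min(1, min(tcross))
  crossings <- which(tcross <= tfac * (1 + 1e-9))
  list(t = tfac, step = tfac * step, crossings = crossings, pairs = pairs)
}

#' Merge Jacobian columns of an on-manifold cluster
#'
#' Implements the common-value rule for the sensitivities of fold-change
#' coordinates locked together on an equality manifold: for every residual
#' row, all member columns are replaced by a common value, so the next
#' trust-region step moves the members identically and the difference stays
#' zero. The default common value is the elementwise mean, which preserves
#' information from both sensitivities and lets a nonzero cluster still
#' travel (e.g. to the origin as \eqn{\lambda \to \infty}); `"max"` uses the
#' member with the largest absolute value; `"zero"` freezes the columns.
#'
#' @param J Jacobian matrix (residuals x parameters).
#' @param cols integer vector of member column indices (>= 2 for mean/max).
#' @param rule `"mean"`, `"max"`, or `"zero"`.
#' @return the modified Jacobian.
#' @export
merge_sensitivities <- function(J, cols, rule = "mean") {
  if (rule == "zero" || length(cols) == 1L) {
    J[, cols] <- 0
    return(J)
  }
  block <- J[, cols, drop = FALSE]
  common <- switch(rule,
    mean = rowMeans(block),
    max = {
      pick <- max.col(abs(block), ties.method = "first")
      block[cbind(seq_len(nrow(block)), pick)]
    },
    stop("unknown merge rule: ", rule, call. = FALSE)
  )
  J[, cols] <- common
  J
}

#' Release a pair's penalty residual
#'
#' When an on-manifold pair is no longer dominated by the regularization
#' (the data gradient points off the manifold), the Jacobian row of that
#' pair's penalty residual has its member entries set to zero so the
#' optimizer can explore leaving the manifold; data-residual rows are
#' untouched.
#'
#' @param J stacked Jacobian.
#' @param row row index of the pair's penalty residual.
#' @param cols member column indices.
#' @return the modified Jacobian.
#' @export
release_pair <- function(J, row, cols) {
  J[row, cols[cols > 0L]] <- 0
  J
}

# Per-pair manifold bookkeeping from unmodified gradients.
# g_chi2 is the gradient of chi^2 over reduced coordinates; col_of maps full
# theta columns to reduced columns.
manifold_state <- function(pairs, delta, spec, g_chi2, col_of) {
  m <- nrow(pairs)
  active <- abs(delta) < spec$epsilon
  data_slope <- numeric(m)
  rate <- numeric(m)
  for (i in seq_len(m)) {
    cj <- if (pairs$col_j[i] > 0L) col_of[pairs$col_j[i]] else 0L
    ck <- if (pairs$col_k[i] > 0L) col_of[pairs$col_k[i]] else 0L
    s <- 0
    r <- 0
    if (cj > 0L) { s <- s + g_chi2[cj]; r <- r + 1 }
    if (ck > 0L) { s <- s - g_chi2[ck]; r <- r + 1 }
    data_slope[i] <- s
    rate[i] <- r
  }
  pen_slope <- spec$lambda * spec$q * spec$epsilon^(spec$q - 1) * rate
  dominated <- active & (abs(data_slope) < pen_slope)
  tibble::tibble(
    parameter = pairs$parameter, j = pairs$j, k = pairs$k,
    col_j = pairs$col_j, col_k = pairs$col_k,
    delta = delta, active = active,
    data_slope = data_slope, penalty_slope = pen_slope,
    dominated = dominated
  )
}

# union-find clusters of theta columns joined by dominated active pairs;
# returns list of integer vectors of *full* column indices (0 = reference)
dominated_clusters <- function(ms) {
  act <- ms[ms$active & ms$dominated, , drop = FALSE]
  if (nrow(act) == 0L) return(list())
  out <- list()
  for (pn in unique(act$parameter)) {
    sub <- act[act$parameter == pn, , drop = FALSE]
    nodes <- unique(c(sub$col_j, sub$col_k))
    parent <- stats::setNames(nodes, nodes)
    find <- function(x) {
      while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
      x
    }
    for (i in seq_len(nrow(sub))) {
      a <- find(sub$col_j[i]); bb <- find(sub$col_k[i])
      if (a != bb) parent[[as.character(max(a, bb))]] <- min(a, bb)
    }
    roots <- vapply(nodes, find, numeric(1))
    for (rt in unique(roots)) {
      out[[length(out) + 1L]] <- sort(nodes[roots == rt])
    }
  }
  out
}

#' Check the three-part optimality criterion
#'
#' A point is optimal when (i) the \eqn{\chi^2} gradient over the base
#' parameters vanishes, and for every penalized pair either (ii) the total
#' directional derivative of the objective along \eqn{e_l - e_n} vanishes
#' while the pair is off its manifold, or (iii) the data directional
#' derivative is strictly dominated by \eqn{\lambda} times the penalty
#' directional derivative (evaluated at \eqn{\epsilon}) while the pair sits
#' on its manifold. Directions locked together by dominated on-manifold
#' clusters are assessed on the quotient space (member gradients summed;
#' clusters tied to the reference dropped).
#'
#' @param mcm a [replicate_model()] object.
#' @param theta flat parameter vector.
#' @param data experiment table.
#' @param spec a [penalty_spec()].
#' @param conditions per-condition constants (see [data_residuals()]).
#' @param control a [fit_control()].
#' @param fixed named base parameters held fixed.
#' @return list with `converged`, the criterion values, and the per-pair
#'   manifold report.
#' @export
check_optimality <- function(mcm, theta, data, spec, conditions = list(),
                             control = fit_control(), fixed = NULL) {
  red <- build_reduction(mcm, fixed = fixed)
  db <- data_residuals(mcm, theta, data, conditions,
                       rtol = control$rtol, atol = control$atol)
  ev <- list(
    res_data = db$res,
    J_data = db$J %*% red$A,
    theta_full = theta
  )
  check_optimality_ev(mcm, ev, spec, control, red)
}

# internal worker operating on precomputed residuals
check_optimality_ev <- function(mcm, ev, spec, control, red) {
  g_chi2 <- drop(2 * crossprod(ev$J_data, ev$res_data))
  nb_cols <- red$col_of[names(mcm$base_idx)]
  crit1 <- if (any(nb_cols > 0L)) max(abs(g_chi2[nb_cols[nb_cols > 0L]])) else 0

  if (spec$lambda == 0) {
    r_cols <- setdiff(which(red$col_of > 0L), which(names(red$col_of) %in% names(mcm$base_idx)))
    crit2 <- if (length(r_cols)) max(abs(g_chi2[red$col_of[r_cols]])) else 0
    return(list(converged = crit1 < control$gtol && crit2 < control$gtol,
                crit1 = crit1, crit2 = crit2, crit3_ok = TRUE,
                manifold = manifold_state(pair_terms(mcm, spec),
                                          pair_deltas(mcm, ev$theta_full,
                                                      pair_terms(mcm, spec)),
                                          spec, g_chi2, red$col_of)))
  }

  pairs <- pair_terms(mcm, spec)
  delta <- pair_deltas(mcm, ev$theta_full, pairs)
  ms <- manifold_state(pairs, delta, spec, g_chi2, red$col_of)
  crit3_ok <- all(ms$dominated[ms$active])

  # total gradient (chi^2 + lambda * smooth penalty terms) on the quotient
  g_nu <- penalty_gradient(mcm, ev$theta_full, spec)
  g_total_full <- stats::setNames(numeric(length(mcm$theta_names)), mcm$theta_names)
  for (nm in mcm$theta_names) {
    cl <- red$col_of[nm]
    if (cl > 0L) g_total_full[nm] <- g_chi2[cl] + spec$lambda * g_nu[nm]
  }
  r_idx <- which(!(names(red$col_of) %in% names(mcm$base_idx)) & red$col_of > 0L)
  clusters <- dominated_clusters(ms)
  in_cluster <- rep(FALSE, length(mcm$theta_names))
  slopes <- numeric()
  for (cl in clusters) {
    in_cluster[cl[cl > 0L]] <- TRUE
    if (any(cl == 0L)) next # tied to the reference: direction removed
    slopes <- c(slopes, sum(g_total_full[cl]))
  }
  singles <- setdiff(r_idx, which(in_cluster))
  slopes <- c(slopes, g_total_full[singles])
  crit2 <- if (length(slopes)) max(abs(slopes)) else 0

  list(converged = crit1 < control$gtol && crit2 < control$gtol && crit3_ok,
       crit1 = crit1, crit2 = crit2, crit3_ok = crit3_ok, manifold = ms)
}

#' Regularized trust-region optimization
#'
#' Minimizes \eqn{L(\theta) = \chi^2(\theta) + \lambda\nu(r)} over the
#' stacked data and penalty residual vector with analytic Jacobian, using
#' Levenberg-Marquardt damping with the nonsmooth adaptations required by
#' the \eqn{L_q} pairwise penalty: every step is truncated so no penalized
#' difference changes sign ([truncate_step()]); pairs that land on an
#' equality manifold are either held together by merging their sensitivity
#' columns ([merge_sensitivities()]) when the penalty dominates the data
#' gradient, or released ([release_pair()]) when it does not; iteration ends
#' when [check_optimality()] passes or the step size stalls.
#'
#' @inheritParams check_optimality
#' @param start named start vector (default [default_theta()]).
#' @param ties optional constrained-refit parameterization: named vector
#'   over the fold-change coordinates with group labels (equal label =
#'   shared value, `0` = fixed at zero). Only allowed with `lambda = 0`.
#' @param multistart optional number of additional perturbed starts; draws
#'   are taken from `multistart_seed` and the best final objective is kept.
#' @param multistart_seed seed recorded in the result.
#' @return an object of class `ct_fit`: final parameters, the
#'   \eqn{\chi^2}/penalty/objective decomposition, convergence diagnostics
#'   and the final manifold state.
#' @export
optimize_regularized <- function(mcm, data, spec, start = default_theta(mcm),
                                 conditions = list(), control = fit_control(),
                                 fixed = NULL, ties = NULL,
                                 multistart = NULL, multistart_seed = 1L) {
  if (!is.null(ties) && spec$lambda > 0) {
    stop("`ties` are only supported for unregularized fits", call. = FALSE)
  }
  check_theta(mcm, start)
  if (any(!is.finite(start))) stop("start vector must be finite", call. = FALSE)

  if (!is.null(multistart) && multistart > 0L) {
    rng <- local({ set.seed(multistart_seed); function(n) stats::rnorm(n, sd = 0.5) })
    starts <- c(list(start), lapply(seq_len(multistart), function(i) {
      s <- start
      s[] <- s + rng(length(s))
      s
    }))
    fits <- lapply(starts, function(s) {
      optimize_regularized(mcm, data, spec, s, conditions, control, fixed, ties)
    })
    best <- fits[[which.min(vapply(fits, function(f) f$objective, numeric(1)))]]
    best$multistart <- list(n = multistart, seed = multistart_seed)
    return(best)
  }

  red <- build_reduction(mcm, fixed = fixed, ties = ties)
  theta_red <- reduce_start(red, start[mcm$theta_names])
  nred <- length(theta_red)

  evalfun <- function(tr) {
    theta_full <- drop(red$A %*% tr) + red$b
    names(theta_full) <- mcm$theta_names
    db <- data_residuals(mcm, theta_full, data, conditions,
                         rtol = control$rtol, atol = control$atol)
    pv <- penalty_value(mcm, theta_full, spec)
    if (spec$lambda > 0) {
      pb <- penalty_residuals(mcm, theta_full, spec)
      res <- c(db$res, pb$res)
      J <- rbind(db$J, pb$J) %*% red$A
    } else {
      pb <- NULL
      res <- db$res
      J <- db$J %*% red$A
    }
    list(res = res, J = J, res_data = db$res, J_data = db$J %*% red$A,
         n_data = length(db$res), chi2 = sum(db$res^2), nu = pv$value,
         theta_full = theta_full,
         objective = sum(db$res^2) + spec$lambda * pv$value)
  }

  ev <- evalfun(theta_red)
  if (!is.finite(ev$objective)) {
    stop("non-finite objective at the start vector", call. = FALSE)
  }
  mu <- control$mu0
  iter <- 0L
  stall <- 0L
  termination <- "max-iter"
  opt <- NULL
  trace <- if (control$trace) list() else NULL

  repeat {
    opt <- check_optimality_ev(mcm, ev, spec, control, red)
    if (opt$converged) {
      termination <- if (spec$lambda > 0 && any(opt$manifold$active)) "manifold" else "gradient"
      break
    }
    if (iter >= control$max_iter) { termination <- "max-iter"; break }

    # --- manifold bookkeeping: releases before merges (fixed convention) ---
    J_mod <- ev$J
    if (spec$lambda > 0) {
      ms <- opt$manifold
      released <- which(ms$active & !ms$dominated)
      for (i in released) {
        cols <- red$col_of[c(ms$col_j[i], ms$col_k[i])[c(ms$col_j[i], ms$col_k[i]) > 0L]]
        J_mod <- release_pair(J_mod, ev$n_data + i, cols)
      }
      for (cl in dominated_clusters(ms)) {
        if (any(cl == 0L)) {
          cols <- red$col_of[cl[cl > 0L]]
          J_mod[, cols] <- 0          # cluster tied to the reference: freeze
        } else {
          J_mod <- merge_sensitivities(J_mod, red$col_of[cl], control$merge_rule)
        }
      }
    }

    g <- drop(crossprod(J_mod, ev$res))
    JtJ <- crossprod(J_mod)
    accepted <- FALSE
    while (!accepted) {
      H <- JtJ + diag(mu, nred)
      step_red <- tryCatch(drop(solve(H, -g)), error = function(e) NULL)
      if (is.null(step_red)) { mu <- mu * 10; next }
      step_full <- drop(red$A %*% step_red)
      names(step_full) <- mcm$theta_names
      if (spec$lambda > 0) {
        tr <- truncate_step(mcm, ev$theta_full, step_full, spec)
        step_red <- tr$t * step_red
        step_full <- tr$t * step_full
      } else tr <- NULL

      cand <- theta_red + step_red
      # land crossings exactly on their manifolds
      if (!is.null(tr) && length(tr$crossings)) {
        full_new <- ev$theta_full + step_full
        for (i in tr$crossings) {
          cj <- tr$pairs$col_j[i]; ck <- tr$pairs$col_k[i]
          if (cj == 0L) {
            cand[red$col_of[ck]] <- 0
          } else if (ck == 0L) {
            cand[red$col_of[cj]] <- 0
          } else {
            mval <- mean(full_new[c(cj, ck)])
            cand[red$col_of[cj]] <- mval
            cand[red$col_of[ck]] <- mval
          }
        }
      }

      ev_new <- tryCatch(evalfun(cand), error = function(e) NULL)
      if (!is.null(ev_new) && is.finite(ev_new$objective)) {
        pred <- ev$objective - sum((ev$res + drop(J_mod %*% (cand - theta_red)))^2)
        rho <- (ev$objective - ev_new$objective) / max(pred, .Machine$double.eps)
        if (ev_new$objective <= ev$objective && rho > control$accept_ratio) {
          accepted <- TRUE
          rel_dec <- (ev$objective - ev_new$objective) / max(1, ev$objective)
          step_norm <- sqrt(sum((cand - theta_red)^2))
          theta_red <- cand
          ev <- ev_new
          mu <- max(mu / 3, 1e-14)
          iter <- iter + 1L
          if (control$trace) {
            trace[[length(trace) + 1L]] <- tibble::tibble(
              iter = iter, objective = ev$objective, chi2 = ev$chi2,
              nu = ev$nu, step_norm = step_norm, mu = mu,
              n_active = if (spec$lambda > 0) sum(abs(pair_deltas(
                mcm, ev$theta_full, pair_terms(mcm, spec))) < spec$epsilon) else 0L)
          }
          if (step_norm < control$xtol * (sqrt(sum(theta_red^2)) + control$xtol)) {
            termination <- "step-size"
          }
          stall <- if (rel_dec < control$ftol) stall + 1L else 0L
          if (stall >= control$stall_iter) termination <- "step-size"
          break
        }
      }
      mu <- mu * 10
      if (mu > control$mu_max) { termination <- "step-size"; break }
    }
    if (!accepted || termination == "step-size") {
      if (termination != "step-size") termination <- "step-size"
      if (!accepted) break
      if (termination == "step-size" && accepted) break
    }
  }

  opt <- check_optimality_ev(mcm, ev, spec, control, red)
  structure(
    list(
      theta = ev$theta_full,
      chi2 = ev$chi2,
      nu = ev$nu,
      penalty = spec$lambda * ev$nu,
      objective = ev$objective,
      iterations = iter,
      termination = termination,
      converged = opt$converged,
      criteria = opt[c("crit1", "crit2", "crit3_ok")],
      manifold = opt$manifold,
      spec = spec,
      control = control,
      fixed = fixed,
      ties = ties,
      trace = if (control$trace) dplyr::bind_rows(trace) else NULL
    ),
    class = "ct_fit"
  )
}

#' @export
print.ct_fit <- function(x, ...) {
  cat("<ct_fit> objective L = ", format(x$objective, digits = 8),
      " (chi2 = ", format(x$chi2, digits = 8),
      ", lambda*nu = ", format(x$penalty, digits = 8), ")\n", sep = "")
  cat("  ", x$iterations, " iteration(s), termination: ", x$termination,
      if (x$converged) " [optimality criteria met]" else "", "\n", sep = "")
  est <- x$theta
  cat("  parameters:\n")
  for (nm in names(est)) cat(sprintf("    %-12s %.6g\n", nm, est[nm]))
  invisible(x)
}

#' Asymptotic standard errors of a fit
#'
#' Standard errors from the observed Fisher information of the data term:
#' with residuals scaled so their sum of squares is the half-weighted
#' \eqn{\chi^2}, the information matrix is \eqn{2 J^T J} and the covariance
#' its inverse. Fold-change coordinates on active manifolds share columns
#' with their partners, so errors there describe the constrained fit.
#'
#' @param mcm a [replicate_model()] object.
#' @param theta parameter vector (typically a fit endpoint).
#' @param data experiment table.
#' @param conditions per-condition constants.
#' @param fixed fixed base parameters (excluded from the information matrix).
#' @param ... passed to [data_residuals()].
#' @return named vector of standard errors over the free coordinates.
#' @export
fit_standard_errors <- function(mcm, theta, data, conditions = list(),
                                fixed = NULL, ...) {
  red <- build_reduction(mcm, fixed = fixed)
  db <- data_residuals(mcm, theta, data, conditions, ...)
  J <- db$J %*% red$A
  info <- 2 * crossprod(J)
  cov <- tryCatch(solve(info), error = function(e) {
    solve(info + diag(1e-8, nrow(info)))
  })
  stats::setNames(sqrt(pmax(diag(cov), 0)), red$red_names)
}
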