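#' Extract cell-type clusters from a fitted parameter vector
#'
#' Cell types whose fold-change values differ by less than `epsilon` are
#' considered equal; the partition per regularized parameter is the
#' transitive closure (union-find) of the pairwise \eqn{|\Delta| < \epsilon}
#' relation, so chains of near-equal values form one cluster even if their
#' extreme members differ slightly more than `epsilon`. A fold change within
#' `epsilon` of zero joins the reference group. The group containing the
#' reference is the zero group: its common value is 0.
#'
#' @param mcm a [replicate_model()] object.
#' @param theta fitted flat parameter vector (typically from a converged
#'   regularized fit).
#' @param epsilon zero threshold, as in [penalty_spec()].
#' @param parameters which specific parameters to partition (default all).
#' @return tibble with columns `parameter`, `cell_type`, `group` (integer id
#'   within parameter, 1 = group containing the lowest cell index), and
#'   `zero` (logical, group tied to the reference).
#' @export
extract_clusters <- function(mcm, theta, epsilon = 1e-10, parameters = NULL) {
  check_theta(mcm, theta)
  parameters <- parameters %||% mcm$specific
  out <- list()
  for (pn in parameters) {
    r <- r_vector(mcm, theta, pn)
    parent <- seq_len(mcm$n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (j in seq_len(mcm$n - 1)) {
      for (k in seq(j + 1, mcm$n)) {
        if (abs(r[j] - r[k]) < epsilon) {
          a <- find(j); b <- find(k)
          if (a != b) parent[max(a, b)] <- min(a, b)
        }
      }
    }
    roots <- vapply(seq_len(mcm$n), find, integer(1))
    group <- match(roots, unique(roots))
    zero_grp <- group[mcm$reference]
    out[[pn]] <- tibble::tibble(
      parameter = pn, cell_type = seq_len(mcm$n), group = group,
      zero = group == zero_grp
    )
  }
  dplyr::bind_rows(out)
}

#' Count the constraints a cluster assignment imposes
#'
#' The degrees of freedom of the likelihood-ratio test comparing a
#' constrained model against the unconstrained fit equal the number of
#' equality constraints: per parameter, every group of `s` cell types
#' removes `s - 1` fold-change parameters, i.e. `k = sum(n - #groups)`.
#' A nonzero two-cell cluster therefore counts 1, while tying both fold
#' changes of a 3-cell-type problem to zero counts 2 (not 3): the pairwise
#' difference constraint is implied. The complementary count of remaining
#' free fold changes per parameter, `m = #groups - 1`, is also returned.
#'
#' @param clusters a cluster assignment from [extract_clusters()].
#' @param n number of cell types.
#' @return list with `k` (constraint count) and `m` (free fold-change count
#'   after constraining).
#' @export
count_constraints <- function(clusters, n) {
  per_par <- dplyr::summarise(
    dplyr::group_by(clusters, .data$parameter),
    groups = dplyr::n_distinct(.data$group),
    .groups = "drop"
  )
  list(k = sum(n - per_par$groups), m = sum(per_par$groups - 1L))
}

# ties vector for optimize_regularized from a cluster assignment:
# "0" = fixed at zero (reference group), otherwise a shared group label
cluster_ties <- function(mcm, clusters) {
  ties <- character()
  for (pn in mcm$specific) {
    sub <- clusters[clusters$parameter == pn, , drop = FALSE]
    if (nrow(sub) == 0L) {
      # unclustered parameter: every fold change its own group
      for (j in setdiff(seq_len(mcm$n), mcm$reference)) {
        ties[paste0("r_", pn, "_", j)] <- paste0(pn, ":solo", j)
      }
      next
    }
    for (j in setdiff(seq_len(mcm$n), mcm$reference)) {
      row <- sub[sub$cell_type == j, , drop = FALSE]
      ties[paste0("r_", pn, "_", j)] <-
        if (row$zero) "0" else paste0(pn, ":", row$group)
    }
  }
  ties
}

#' Refit with cluster constraints and no regularization
#'
#' Reparameterizes the model so that each cluster shares a single
#' fold-change value (the reference group fixed at zero) and reoptimizes
#' with `lambda = 0`, yielding unbiased parameter estimates and the
#' constrained \eqn{\chi^2} used by the likelihood-ratio test.
#'
#' @inheritParams extract_clusters
#' @param data experiment table.
#' @param clusters cluster assignment from [extract_clusters()].
#' @param start start vector (typically the regularized fit's endpoint).
#' @param conditions,control,fixed passed to [optimize_regularized()].
#' @return a `ct_fit` whose `theta` satisfies the cluster constraints
#'   exactly.
#' @export
constrained_refit <- function(mcm, data, clusters, start = default_theta(mcm),
                              conditions = list(), control = fit_control(),
                              fixed = NULL) {
  ties <- cluster_ties(mcm, clusters)
  optimize_regularized(mcm, data, penalty_spec(lambda = 0), start = start,
                       conditions = conditions, control = control,
                       fixed = fixed, ties = ties)
}

#' Likelihood-ratio model selection over a scan
#'
#' For each candidate constrained model the test statistic is
#' \eqn{D = s\,(\chi^2_{constrained} - \chi^2_{full})} with `stat_scale`
#' \eqn{s = 2} by default (the \eqn{\chi^2} of this package carries a 1/2
#' factor, so \eqn{D} is \eqn{-2\Delta\log L} and Wilks' theorem applies).
#' `D` is compared against the upper-\eqn{\alpha} quantile of the
#' chi-squared distribution with as many degrees of freedom as the model has
#' constraints (`dof = "constraints"`); `dof = "free"` instead uses the
#' remaining free fold-change count, the alternative bookkeeping convention.
#' The selected model is the one at the largest regularization strength that
#' is not rejected; unconstrained candidates (`k = 0`) are accepted iff
#' their statistic is zero within tolerance.
#'
#' @param scan list of per-lambda records, each with elements `lambda`,
#'   `clusters` (from [extract_clusters()]), and `chi2` (constrained-refit
#'   value).
#' @param full_fit the unconstrained `lambda = 0` fit (a `ct_fit`), or its
#'   \eqn{\chi^2} value.
#' @param n number of cell types.
#' @param alpha test level (default 0.05).
#' @param dof `"constraints"` (default) or `"free"`.
#' @param stat_scale multiplier converting the objective difference into the
#'   test statistic (default 2).
#' @param zero_tol acceptance tolerance on `D` for models without
#'   constraints.
#' @return tibble with one row per candidate: `lambda`, `k`, `m`, `D`,
#'   `p_value`, `rejected`, `selected`.
#' @export
lrt_select <- function(scan, full_fit, n, alpha = 0.05,
                       dof = c("constraints", "free"), stat_scale = 2,
                       zero_tol = NULL) {
  if (length(scan) == 0L) stop("empty scan", call. = FALSE)
  dof <- match.arg(dof)
  chi2_full <- if (inherits(full_fit, "ct_fit")) full_fit$chi2 else full_fit
  zero_tol <- zero_tol %||% (1e-6 * max(1, abs(chi2_full)))

  rows <- lapply(scan, function(rec) {
    cc <- count_constraints(rec$clusters, n)
    D <- max(0, stat_scale * (rec$chi2 - chi2_full))
    df <- if (dof == "constraints") cc$k else cc$m
    if (cc$k == 0L || df == 0L) {
      # unconstrained candidate (or zero test dof): accept iff it does not
      # worsen the objective at all
      p <- if (D <= zero_tol) 1 else 0
      rejected <- D > zero_tol
    } else {
      p <- stats::pchisq(D, df = df, lower.tail = FALSE)
      rejected <- p < alpha
    }
    tibble::tibble(lambda = rec$lambda, k = cc$k, m = cc$m, D = D,
                   p_value = p, rejected = rejected)
  })
  tab <- dplyr::bind_rows(rows)
  tab$selected <- FALSE
  ok <- which(!tab$rejected)
  if (length(ok)) tab$selected[max(ok)] <- TRUE
  tab
}

#' Default grid of regularization strengths
#'
#' 30 log-spaced values between 1 and 1e4, the grid used for
#' application-scale problems; bounds and resolution are configurable.
#'
#' @param min,max grid bounds.
#' @param n number of values.
#' @export
default_lambda_grid <- function(min = 1, max = 1e4, n = 30L) {
  10^seq(log10(min), log10(max), length.out = n)
}

#' Two-step model selection: lambda scan, refits, likelihood-ratio test
#'
#' Runs [optimize_regularized()] for an ascending grid of regularization
#' strengths (warm-starting each fit from the previous endpoint when
#' enabled), extracts the cluster assignment at each endpoint, refits each
#' constrained model without regularization for unbiased estimates, and
#' selects the parsimonious model as the largest `lambda` whose constrained
#' model the likelihood-ratio test does not reject at level `alpha`.
#'
#' @inheritParams constrained_refit
#' @param spec a [penalty_spec()]; its `lambda` entry is ignored in favour
#'   of the grid.
#' @param lambdas ascending grid of regularization strengths.
#' @param warm_start warm-start each fit from the previous endpoint
#'   (otherwise every fit starts from the unregularized optimum).
#' @param multistart,multistart_seed optional per-lambda multistart, passed
#'   to [optimize_regularized()] (new optima can arise along the path).
#' @param alpha,dof,stat_scale see [lrt_select()].
#' @return an object of class `ct_scan`: the per-lambda selection table,
#'   cluster assignments, regularization path, fits, the full fit and the
#'   selected model.
#' @export
lambda_scan <- function(mcm, data, spec = penalty_spec(),
                        lambdas = default_lambda_grid(),
                        start = default_theta(mcm), conditions = list(),
                        control = fit_control(), fixed = NULL,
                        warm_start = TRUE, alpha = 0.05,
                        dof = c("constraints", "free"), stat_scale = 2,
                        multistart = NULL, multistart_seed = 1L) {
  dof <- match.arg(dof)
  lambdas <- sort(unique(lambdas))
  full <- optimize_regularized(mcm, data, penalty_spec(
    q = spec$q, lambda = 0, epsilon = spec$epsilon, mode = spec$mode,
    regularized = spec$regularized
  ), start = start, conditions = conditions, control = control, fixed = fixed)

  prev <- full$theta
  recs <- vector("list", length(lambdas))
  fits <- vector("list", length(lambdas))
  refits <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    li <- lambdas[i]
    spec_i <- penalty_spec(q = spec$q, lambda = li, epsilon = spec$epsilon,
                           mode = spec$mode, regularized = spec$regularized)
    if (li == 0) {
      fit <- full
    } else {
      fit <- optimize_regularized(mcm, data, spec_i,
                                  start = if (warm_start) prev else full$theta,
                                  conditions = conditions, control = control,
                                  fixed = fixed, multistart = multistart,
                                  multistart_seed = multistart_seed)
    }
    if (warm_start) prev <- fit$theta
    cl <- extract_clusters(mcm, fit$theta, epsilon = spec$epsilon,
                           parameters = spec$regularized %||% mcm$specific)
    cc <- count_constraints(cl, mcm$n)
    refit <- if (cc$k == 0L) full else {
      constrained_refit(mcm, data, cl, start = fit$theta,
                        conditions = conditions, control = control,
                        fixed = fixed)
    }
    fits[[i]] <- fit
    refits[[i]] <- refit
    recs[[i]] <- list(lambda = li, clusters = cl, chi2 = refit$chi2)
  }

  tab <- lrt_select(recs, full, mcm$n, alpha = alpha, dof = dof,
                    stat_scale = stat_scale)
  tab$objective_reg <- vapply(fits, function(f) f$objective, numeric(1))
  tab$chi2_refit <- vapply(refits, function(f) f$chi2, numeric(1))

  sel <- which(tab$selected)
  path <- dplyr::bind_rows(lapply(seq_along(lambdas), function(i) {
    th <- fits[[i]]$theta
    r_names <- setdiff(mcm$theta_names, names(mcm$base_idx))
    tibble::tibble(lambda = lambdas[i], parameter = r_names,
                   value = unname(th[r_names]))
  }))

  structure(
    list(
      table = tab,
      clusters = lapply(recs, `[[`, "clusters"),
      fits = fits,
      refits = refits,
      full_fit = full,
      path = path,
      selected = if (length(sel)) sel else NA_integer_,
      selected_clusters = if (length(sel)) recs[[sel]]$clusters else NULL,
      selected_fit = if (length(sel)) refits[[sel]] else NULL,
      mcm = mcm,
      spec = spec,
      alpha = alpha,
      dof = dof,
      stat_scale = stat_scale
    ),
    class = "ct_scan"
  )
}

#' @export
print.ct_scan <- function(x, ...) {
  cat("<ct_scan> ", nrow(x$table), " regularization strengths, mode: ",
      x$spec$mode, ", q = ", x$spec$q, "\n", sep = "")
  print(x$table, n = nrow(x$table))
  if (!is.na(x$selected)) {
    cat("selected lambda* = ", format(x$table$lambda[x$selected], digits = 4),
        "; clusters:\n", sep = "")
    cl <- x$selected_clusters
    for (pn in unique(cl$parameter)) {
      sub <- cl[cl$parameter == pn, ]
      grp <- split(sub$cell_type, sub$group)
      lab <- vapply(grp, function(g) paste0("{", paste(g, collapse = ","), "}"),
                    character(1))
      cat("  ", pn, ": ", paste(lab, collapse = " "), "\n", sep = "")
    }
  }
  invisible(x)
}
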