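#' Toy decay scenario
#'
#' The minimal test bed for the clustered penalty: exponential decay
#' \eqn{\dot x = -p\,x}, \eqn{x(0) = 1}, observed directly
#' (\eqn{g(x, p) = x}) in three cell types whose true decay rates are
#' \eqn{\log_{10} p = -1.5, -1.3, -1.2}, i.e. fold changes
#' \eqn{r^{(2)} = 0.2}, \eqn{r^{(3)} = 0.3}: cell types 2 and 3 carry a
#' similar mutation, clearly different from cell type 1. Observation noise
#' is Gaussian with \eqn{\log_{10}\sigma = -1.3} (\eqn{\sigma \approx
#' 0.0501}). The default grid of 11 time points t = 0..10 with one replicate
#' puts the 2-vs-3 distinction near the noise floor while cell type 1
#' separates clearly.
#'
#' @param seed simulation seed stored in the scenario.
#' @param times observation time grid.
#' @param replicates replicate measurements per time point.
#' @param log_sigma log10 of the observation noise standard deviation.
#' @param free_reference if `FALSE`, the scenario records that the reference
#'   decay rate is known: fits receive `fixed = c(p = -1.5)` and the
#'   parameter space reduces to the two fold changes.
#' @return an object of class `ct_scenario`.
#' @export
toy_scenario <- function(seed = 1L, times = 0:10, replicates = 1L,
                         log_sigma = -1.3, free_reference = TRUE) {
  decay <- ode_model(
    states = "x",
    odes = list(x = ~ -p * x),
    observables = list(x_obs = ~x),
    parameters = c(p = -1),
    initials = list(x = 1)
  )
  mcm <- replicate_model(decay, n = 3, specific = "p", reference = 1L)
  truth <- default_theta(mcm)
  truth["p"] <- -1.5
  truth["r_p_2"] <- 0.2
  truth["r_p_3"] <- 0.3
  structure(
    list(
      name = "toy_decay",
      mcm = mcm,
      truth = truth,
      sigma = 10^log_sigma,
      times = times,
      replicates = as.integer(replicates),
      conditions = list(),
      design = tidyr::expand_grid(
        cell_type = 1:3, condition = "1",
        observable = "x_obs", time = times,
        replicate = seq_len(replicates)
      ),
      fixed = if (free_reference) NULL else c(p = -1.5),
      seed = as.integer(seed)
    ),
    class = "ct_scenario"
  )
}

#' Receptor-trafficking scenario with planted parameter clusters
#'
#' A small synthetic receptor model for simulation studies of the full
#' selection workflow: ligand binding at the cell surface, internalization
#' of free and bound receptor, recycling and lysosomal degradation, observed
#' as total surface and total internalized receptor in a dose-response by
#' time-course design. It is a bespoke stand-in at desk scale that preserves
#' the structure of benchmark receptor models (multiple observables, doses,
#' planted cell-type clusters), not a reproduction of any published model.
#'
#' Fold-change ground truth is planted per specific parameter as a partition
#' of the cell types with one value per group; the group containing the
#' reference must have value 0.
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param planted named list per specific parameter:
#'   `list(groups = list(...), values = c(...))`. Defaults plant a nonzero
#'   cluster excluding the reference, a cluster including it, and one fully
#'   shared parameter.
#' @param seed simulation seed stored in the scenario.
#' @param doses ligand doses (condition constants).
#' @param times observation time grid.
#' @param sigma observation noise standard deviation.
#' @param fixed_params base parameters treated as known and held at their
#'   true values during fitting (recorded in the scenario's `fixed` field),
#'   the usual practice for rate constants that are structurally
#'   non-identifiable from the observed compartments.
#' @return an object of class `ct_scenario` whose `truth` encodes the
#'   planted partitions.
#' @export
receptor_scenario <- function(n_cell_types = 5L, planted = NULL, seed = 1L,
                              doses = c(1, 10), times = c(0, 10, 30, 60, 120),
                              sigma = 0.05,
                              fixed_params = c("kon", "krec")) {
  n <- as.integer(n_cell_types)
  model <- ode_model(
    states = c("R", "C", "Ri", "Ci"),
    odes = list(
      R = ~ koff * C - kon * L * R - kintR * R + krec * Ri,
      C = ~ kon * L * R - koff * C - kintC * C,
      Ri = ~ kintR * R - krec * Ri - kdeg * Ri,
      Ci = ~ kintC * C - kdeg * Ci
    ),
    observables = list(
      surface = ~ R + C,
      internal = ~ Ri + Ci
    ),
    parameters = c(R0 = 0, kon = -1, koff = -1, kintR = -1.7,
                   kintC = -0.7, krec = -1.3, kdeg = -1.3),
    initials = list(R = ~R0, C = 0, Ri = 0, Ci = 0),
    inputs = list(L = ~dose),
    condition_vars = "dose"
  )
  if (is.null(planted)) {
    planted <- list(
      R0 = list(groups = list(1, 2:3, 4:n), values = c(0, 0.5, -0.5)),
      kintC = list(groups = list(1:2, 3:n), values = c(0, 0.6)),
      kdeg = list(groups = list(1:n), values = 0)
    )
    if (n < 4L) {
      planted <- list(
        R0 = list(groups = list(1, 2:n), values = c(0, 0.5)),
        kintC = list(groups = list(1:n), values = 0)
      )
    }
  }
  specific <- names(planted)
  mcm <- replicate_model(model, n = n, specific = specific, reference = 1L)
  truth <- default_theta(mcm)
  for (pn in specific) {
    pl <- planted[[pn]]
    if (length(pl$groups) > n) {
      stop("infeasible partition for '", pn, "': more groups than cell types",
           call. = FALSE)
    }
    members <- as.integer(sort(unlist(pl$groups)))
    if (!identical(members, seq_len(n))) {
      stop("groups for '", pn, "' must partition 1..n", call. = FALSE)
    }
    for (g in seq_along(pl$groups)) {
      grp <- pl$groups[[g]]
      if (mcm$reference %in% grp && pl$values[g] != 0) {
        stop("the group containing the reference must have value 0 ('",
             pn, "')", call. = FALSE)
      }
      for (j in setdiff(grp, mcm$reference)) {
        truth[mcm$r_index[pn, j]] <- pl$values[g]
      }
    }
  }
  conditions <- stats::setNames(
    lapply(doses, function(d) list(dose = d)),
    paste0("dose", seq_along(doses))
  )
  structure(
    list(
      name = "receptor_trafficking",
      mcm = mcm,
      truth = truth,
      sigma = sigma,
      times = times,
      replicates = 1L,
      conditions = conditions,
      design = tidyr::expand_grid(
        cell_type = seq_len(n),
        condition = names(conditions),
        observable = names(model$observables),
        time = times,
        replicate = 1L
      ),
      planted = planted,
      fixed = if (length(fixed_params)) truth[fixed_params] else NULL,
      seed = as.integer(seed)
    ),
    class = "ct_scenario"
  )
}

#' @export
print.ct_scenario <- function(x, ...) {
  cat("<ct_scenario> ", x$name, ": ", x$mcm$n, " cell types, ",
      nrow(x$design), " design points, sigma = ", signif(x$sigma, 4),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate an experiment table from a scenario
#'
#' Simulates the scenario's model at its true parameters over the design and
#' adds i.i.d. Gaussian observation noise. Regenerating with the same seed
#' reproduces the table bit-for-bit.
#'
#' @param scenario a `ct_scenario`.
#' @param seed noise seed; defaults to the scenario's stored seed.
#' @param noiseless if `TRUE`, return the exact model output (the `sigma`
#'   column keeps the scenario's value so the table stays valid).
#' @return an experiment table tibble.
#' @export
simulate_scenario <- function(scenario, seed = scenario$seed,
                              noiseless = FALSE) {
  mcm <- scenario$mcm
  des <- scenario$design
  y <- numeric(nrow(des))
  key <- paste(des$cell_type, des$condition, sep = "\r")
  for (kk in unique(key)) {
    rows <- which(key == kk)
    ct <- des$cell_type[rows[1]]
    cond <- scenario$conditions[[des$condition[rows[1]]]] %||% list()
    tt <- sort(unique(des$time[rows]))
    traj <- integrate_with_sensitivities(mcm, scenario$truth, ct, tt, cond)
    obs <- eval_observables(mcm, traj, des$observable[rows], cond)
    for (r in rows) {
      y[r] <- obs[[des$observable[r]]]$y[match(des$time[r], tt)]
    }
  }
  out <- tibble::tibble(
    time = des$time,
    observable = des$observable,
    value = y,
    sigma = scenario$sigma,
    cell_type = des$cell_type,
    condition = des$condition
  )
  if (!noiseless) {
    set.seed(seed)
    out$value <- out$value + stats::rnorm(nrow(out), sd = scenario$sigma)
  }
  out
}

# truth table of zero quantities for a scenario: every fold change and every
# pairwise difference of one parameter, with its true-zero flag
scenario_truth_table <- function(scenario) {
  mcm <- scenario$mcm
  out <- list()
  for (pn in mcm$specific) {
    r <- r_vector(mcm, scenario$truth, pn)
    for (j in setdiff(seq_len(mcm$n), mcm$reference)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        parameter = pn, quantity = paste0("r_", pn, "_", j),
        type = "fold_change", j = j, k = NA_integer_,
        truth_zero = abs(r[j]) < 1e-12
      )
    }
    cmb <- utils::combn(mcm$n, 2)
    for (i in seq_len(ncol(cmb))) {
      j <- cmb[1, i]; k <- cmb[2, i]
      out[[length(out) + 1L]] <- tibble::tibble(
        parameter = pn, quantity = paste0("d_", pn, "_", j, "_", k),
        type = "difference", j = j, k = k,
        truth_zero = abs(r[j] - r[k]) < 1e-12
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Run a simulation study of the selection workflow
#'
#' Generates `n_datasets` datasets from freshly seeded scenarios, runs the
#' full two-step selection ([lambda_scan()]) on each, and counts how often
#' every fold-change parameter and every pairwise difference is constrained
#' to zero in the selected parsimonious model, against the planted ground
#' truth. Individual run failures are recorded, not fatal.
#'
#' @param scenario_fun function(seed) returning a `ct_scenario`, e.g.
#'   [toy_scenario()] or [receptor_scenario()] (wrap to set options).
#' @param n_datasets number of simulated datasets.
#' @param method `"clustered"` or `"standard"` penalty mode.
#' @param lambdas regularization-strength grid.
#' @param seeds dataset seeds (default `1:n_datasets`).
#' @param q pseudonorm exponent.
#' @param alpha test level.
#' @param control a [fit_control()].
#' @return an object of class `ct_study` with the per-quantity tally, the
#'   per-run outcomes, and any failures.
#' @export
run_study <- function(scenario_fun, n_datasets, method = "clustered",
                      lambdas = default_lambda_grid(0.1, 1000, 13L),
                      seeds = NULL, q = 0.8, alpha = 0.05,
                      control = fit_control()) {
  stopifnot(n_datasets >= 1L)
  seeds <- seeds %||% seq_len(n_datasets)
  runs <- list()
  failures <- list()
  truth <- NULL
  for (s in seeds) {
    sc <- scenario_fun(s)
    if (is.null(truth)) truth <- scenario_truth_table(sc)
    res <- tryCatch({
      data <- simulate_scenario(sc)
      scan <- lambda_scan(sc$mcm, data,
                          penalty_spec(q = q, lambda = 1, mode = method),
                          lambdas = lambdas, conditions = sc$conditions,
                          control = control, fixed = sc$fixed, alpha = alpha)
      cl <- scan$selected_clusters
      zero <- vapply(seq_len(nrow(truth)), function(i) {
        sub <- cl[cl$parameter == truth$parameter[i], , drop = FALSE]
        if (truth$type[i] == "fold_change") {
          sub$zero[sub$cell_type == truth$j[i]]
        } else {
          sub$group[sub$cell_type == truth$j[i]] ==
            sub$group[sub$cell_type == truth$k[i]]
        }
      }, logical(1))
      tibble::tibble(seed = s, quantity = truth$quantity, zero = zero,
                     lambda_star = scan$table$lambda[scan$selected])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        seed = s, message = conditionMessage(res))
    } else {
      runs[[length(runs) + 1L]] <- res
    }
  }
  runs <- dplyr::bind_rows(runs)
  tally <- dplyr::left_join(
    truth,
    dplyr::summarise(dplyr::group_by(runs, .data$quantity),
                     times_zero = sum(.data$zero), .groups = "drop"),
    by = "quantity"
  )
  tally$times_zero[is.na(tally$times_zero)] <- 0L
  tally$n_runs <- length(unique(runs$seed))
  structure(
    list(tally = tally, runs = runs,
         failures = dplyr::bind_rows(failures),
         method = method, q = q, seeds = seeds),
    class = "ct_study"
  )
}

#' @export
print.ct_study <- function(x, ...) {
  cat("<ct_study> ", x$method, " mode, ", length(x$seeds), " dataset(s), ",
      nrow(x$failures), " failure(s)\n", sep = "")
  print(x$tally, n = nrow(x$tally))
  invisible(x)
}
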