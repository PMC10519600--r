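#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a regularized fit
#'
#' One row per free parameter with its estimate and role (base parameter or
#' fold change).
#'
#' @param x a `ct_fit` from [optimize_regularized()].
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `type`, `cell_type`.
#' @export
tidy.ct_fit <- function(x, ...) {
  nm <- names(x$theta)
  is_r <- grepl("^r_", nm)
  cell <- rep(NA_integer_, length(nm))
  cell[is_r] <- as.integer(sub(".*_(\\d+)$", "\\1", nm[is_r]))
  tibble::tibble(
    term = nm,
    estimate = unname(x$theta),
    type = ifelse(is_r, "fold_change", "base"),
    cell_type = cell
  )
}

#' @rdname tidy.ct_fit
#' @export
glance.ct_fit <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2,
    penalty_value = x$nu,
    penalty = x$penalty,
    objective = x$objective,
    lambda = x$spec$lambda,
    q = x$spec$q,
    mode = x$spec$mode,
    iterations = x$iterations,
    termination = x$termination,
    converged = x$converged,
    n_active = sum(x$manifold$active)
  )
}

#' Tidy a lambda scan
#'
#' @param x a `ct_scan` from [lambda_scan()].
#' @param ... unused.
#' @return the per-lambda selection table as a tibble.
#' @export
tidy.ct_scan <- function(x, ...) x$table

#' @rdname tidy.ct_scan
#' @export
glance.ct_scan <- function(x, ...) {
  sel <- x$selected
  tibble::tibble(
    n_lambda = nrow(x$table),
    mode = x$spec$mode,
    q = x$spec$q,
    alpha = x$alpha,
    lambda_star = if (!is.na(sel)) x$table$lambda[sel] else NA_real_,
    k_star = if (!is.na(sel)) x$table$k[sel] else NA_integer_,
    chi2_full = x$full_fit$chi2
  )
}

#' Regularization path of a scan
#'
#' Long table of every fold-change parameter and every pairwise difference
#' against the regularization strength, suitable for path plots and export.
#'
#' @param scan a `ct_scan`.
#' @return tibble with columns `lambda`, `quantity`, `type`, `value`.
#' @export
regularization_path <- function(scan) {
  mcm <- scan$mcm
  rows <- lapply(seq_len(nrow(scan$table)), function(i) {
    th <- scan$fits[[i]]$theta
    lam <- scan$table$lambda[i]
    out <- list()
    for (pn in mcm$specific) {
      r <- r_vector(mcm, th, pn)
      for (j in setdiff(seq_len(mcm$n), mcm$reference)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          lambda = lam, quantity = paste0("r_", pn, "_", j),
          type = "fold_change", value = r[j])
      }
      cmb <- utils::combn(mcm$n, 2)
      for (c2 in seq_len(ncol(cmb))) {
        j <- cmb[1, c2]; k <- cmb[2, c2]
        out[[length(out) + 1L]] <- tibble::tibble(
          lambda = lam, quantity = paste0("d_", pn, "_", j, "_", k),
          type = "difference", value = r[j] - r[k])
      }
    }
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' Plot the regularization path and test statistic of a scan
#'
#' Top panel: every fold change and pairwise difference against
#' \eqn{\lambda} (log scale); quantities collapse onto shared values as the
#' clustered penalty takes hold. Bottom panel: the likelihood-ratio test
#' statistic with the selected \eqn{\lambda^*} marked.
#'
#' @param object a `ct_scan`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ct_scan <- function(object, ...) {
  path <- regularization_path(object)
  sel_lambda <- if (!is.na(object$selected)) {
    object$table$lambda[object$selected]
  } else NA_real_
  p <- ggplot2::ggplot(path, ggplot2::aes(x = .data$lambda, y = .data$value,
                                          colour = .data$quantity,
                                          linetype = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "fold change / difference",
                  title = "Regularization path") +
    ggplot2::theme_minimal()
  if (!is.na(sel_lambda)) {
    p <- p + ggplot2::geom_vline(xintercept = sel_lambda, linetype = 3)
  }
  p
}

#' Tidy a simulation study
#'
#' @param x a `ct_study` from [run_study()].
#' @param ... unused.
#' @return the tally tibble with zero-constraint rates per quantity.
#' @export
tidy.ct_study <- function(x, ...) {
  out <- x$tally
  out$rate <- out$times_zero / pmax(out$n_runs, 1L)
  out
}

#' @rdname tidy.ct_study
#' @export
glance.ct_study <- function(x, ...) {
  t <- tidy(x)
  pos <- t[t$truth_zero, , drop = FALSE]
  neg <- t[!t$truth_zero, , drop = FALSE]
  tibble::tibble(
    method = x$method,
    q = x$q,
    n_runs = max(t$n_runs),
    n_failures = nrow(x$failures),
    tpr = if (nrow(pos)) sum(pos$times_zero) / sum(pos$n_runs) else NA_real_,
    fpr = if (nrow(neg)) sum(neg$times_zero) / sum(neg$n_runs) else NA_real_
  )
}

#' Histogram of zero-constraint counts in a study
#'
#' Mirrors the usual presentation of simulation studies of sparsity
#' recovery: how often each fold change and each pairwise difference was
#' constrained to zero in the selected model, with the ground truth shaded.
#'
#' @param object a `ct_study`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ct_study <- function(object, ...) {
  t <- tidy(object)
  ggplot2::ggplot(t, ggplot2::aes(x = .data$quantity, y = .data$times_zero,
                                  fill = .data$truth_zero)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = max(t$n_runs), linetype = 3) +
    ggplot2::labs(x = NULL, y = "times constrained to zero",
                  fill = "truly zero") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot data and fitted trajectories
#'
#' @param mcm a [replicate_model()] object.
#' @param theta fitted parameters.
#' @param data experiment table.
#' @param conditions per-condition constants.
#' @param n_grid number of time points for the fitted curves.
#' @return a ggplot object: points with error bars per cell type and the
#'   model trajectories.
#' @export
plot_fit <- function(mcm, theta, data, conditions = list(), n_grid = 101L) {
  data <- validate_experiment_table(data, mcm)
  tmax <- max(data$time)
  grid <- seq(0, tmax, length.out = n_grid)
  curves <- list()
  for (ct in sort(unique(data$cell_type))) {
    for (cond in unique(data$condition[data$cell_type == ct])) {
      traj <- integrate_with_sensitivities(mcm, theta, ct, grid,
                                           conditions[[cond]] %||% list())
      obs <- eval_observables(mcm, traj,
                              unique(data$observable), conditions[[cond]] %||% list())
      for (ob in names(obs)) {
        curves[[length(curves) + 1L]] <- tibble::tibble(
          time = grid, value = obs[[ob]]$y, observable = ob,
          cell_type = ct, condition = cond)
      }
    }
  }
  curves <- dplyr::bind_rows(curves)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = factor(.data$cell_type))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$sigma,
                                          ymax = .data$value + .data$sigma),
                             size = 0.2) +
    ggplot2::geom_line(data = curves) +
    ggplot2::facet_grid(observable ~ condition, scales = "free_y") +
    ggplot2::labs(colour = "cell type") +
    ggplot2::theme_minimal()
}
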