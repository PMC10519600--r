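#' Replicate an ODE model across cell types
#'
#' Copies a single-cell-type model across `n` cell types that share the model
#' structure and all non-specific parameters. Each parameter in `specific` is
#' allowed to differ between cell types via log10 fold-change parameters
#' \eqn{r_i^{(j)}}: \deqn{\log_{10} p_i^{(j)} = \log_{10} p_i^{(1)} + r_i^{(j)},}
#' with \eqn{r_i^{(1)} \equiv 0} for the technical reference cell type, which
#' is never a free parameter. The free parameter vector therefore consists of
#' the base parameters (declaration order) followed by
#' \eqn{|specific| \times (n-1)} fold changes, grouped by parameter with cell
#' types ascending.
#'
#' @param model an [ode_model()].
#' @param n number of cell types (>= 2).
#' @param specific character vector of parameter names allowed to be
#'   cell-type specific (must be log-scale parameters).
#' @param reference index of the technical reference cell type (default 1).
#'   With the clustered penalty this choice is computationally convenient but
#'   does not affect results; see [relabel_reference()].
#'
#' @return An object of class `multicell_model`.
#' @examples
#' decay <- ode_model(
#'   states = "x", odes = list(x = ~ -p * x),
#'   observables = list(x_obs = ~x),
#'   parameters = c(p = -1), initials = list(x = 1)
#' )
#' mcm <- replicate_model(decay, n = 3, specific = "p")
#' mcm$theta_names # "p" "r_p_2" "r_p_3"
#' @export
replicate_model <- function(model, n, specific, reference = 1L) {
  stopifnot(inherits(model, "ode_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  reference <- as.integer(reference)
  if (reference < 1L || reference > n) {
    stop("`reference` must be in 1..n", call. = FALSE)
  }
  specific <- as.character(specific)
  unknown <- setdiff(specific, model$parameters)
  if (length(unknown)) {
    stop("unknown parameter name(s) in `specific`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  nonlog <- specific[!model$log_scale[specific]]
  if (length(nonlog)) {
    stop("specific parameters must be log-scale: ",
         paste(nonlog, collapse = ", "), call. = FALSE)
  }

  base_names <- model$parameters
  cells <- seq_len(n)
  r_names <- unlist(lapply(specific, function(pn) {
    paste0("r_", pn, "_", setdiff(cells, reference))
  }))
  theta_names <- c(base_names, r_names)

  # r_index[param, cell]: position of r in theta, 0 for the reference
  r_index <- matrix(0L, nrow = length(specific), ncol = n,
                    dimnames = list(specific, NULL))
  for (pn in specific) {
    for (j in setdiff(cells, reference)) {
      r_index[pn, j] <- match(paste0("r_", pn, "_", j), theta_names)
    }
  }

  structure(
    list(
      model = model,
      n = n,
      reference = reference,
      specific = specific,
      theta_names = theta_names,
      base_idx = stats::setNames(seq_along(base_names), base_names),
      r_index = r_index
    ),
    class = "multicell_model"
  )
}

#' @export
print.multicell_model <- function(x, ...) {
  cat("<multicell_model> ", x$n, " cell types (reference ", x$reference, "), ",
      length(x$specific), " specific parameter(s): ",
      paste(x$specific, collapse = ", "), "\n", sep = "")
  cat("  free parameters (", length(x$theta_names), "): ",
      paste(x$theta_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default parameter vector for a replicated model
#'
#' Base parameters at the model's declared defaults, all fold changes at 0.
#'
#' @param mcm a [replicate_model()] object.
#' @return named numeric vector in the flat theta ordering.
#' @export
default_theta <- function(mcm) {
  th <- stats::setNames(numeric(length(mcm$theta_names)), mcm$theta_names)
  th[names(mcm$base_idx)] <- mcm$model$default[names(mcm$base_idx)]
  th
}

#' Expand the flat parameter vector for one cell type
#'
#' Applies the fold-change transform: a specific parameter `i` in cell type
#' `j` equals `base_i + r_i^(j)` on the log10 scale; the reference cell type
#' returns the base values unchanged; non-specific parameters are shared.
#'
#' @param mcm a [replicate_model()] object.
#' @param theta named numeric parameter vector (see [default_theta()]).
#' @param cell_type cell-type index in 1..n.
#' @return named numeric vector over the model's parameters, estimation scale.
#' @export
expand_parameters <- function(mcm, theta, cell_type) {
  check_theta(mcm, theta)
  cell_type <- as.integer(cell_type)
  stopifnot(cell_type >= 1L, cell_type <= mcm$n)
  est <- theta[names(mcm$base_idx)]
  if (cell_type != mcm$reference) {
    for (pn in mcm$specific) {
      est[pn] <- est[pn] + theta[mcm$r_index[pn, cell_type]]
    }
  }
  est
}

check_theta <- function(mcm, theta) {
  if (is.null(names(theta))) {
    if (length(theta) != length(mcm$theta_names)) {
      stop("parameter vector has wrong length", call. = FALSE)
    }
  } else {
    missing <- setdiff(mcm$theta_names, names(theta))
    if (length(missing)) {
      stop("parameter vector incomplete; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Change the technical reference cell type
#'
#' Re-expresses the model and a parameter point with a different reference:
#' `base_i' = base_i + r_i^(new)` and `r_i^(j)' = r_i^(j) - r_i^(new)`. The
#' per-cell-type expanded parameters are numerically identical before and
#' after, which is the sense in which the clustered penalty makes the
#' reference choice purely technical.
#'
#' @param mcm a [replicate_model()] object.
#' @param new_reference new reference index in 1..n.
#' @param theta parameter vector at the current reference.
#' @return list with elements `model` (relabelled `multicell_model`) and
#'   `theta` (the equivalent parameter vector).
#' @export
relabel_reference <- function(mcm, new_reference, theta) {
  new_reference <- as.integer(new_reference)
  stopifnot(new_reference >= 1L, new_reference <= mcm$n)
  check_theta(mcm, theta)
  m2 <- replicate_model(mcm$model, mcm$n, mcm$specific, reference = new_reference)
  th2 <- stats::setNames(numeric(length(m2$theta_names)), m2$theta_names)
  th2[names(m2$base_idx)] <- theta[names(mcm$base_idx)]
  for (pn in mcm$specific) {
    r_new <- r_of(mcm, theta, pn, new_reference)
    th2[pn] <- theta[pn] + r_new
    for (j in setdiff(seq_len(m2$n), new_reference)) {
      th2[m2$r_index[pn, j]] <- r_of(mcm, theta, pn, j) - r_new
    }
  }
  list(model = m2, theta = th2)
}

# fold-change value of parameter pn in cell j (0 at the reference)
r_of <- function(mcm, theta, pn, j) {
  idx <- mcm$r_index[pn, j]
  if (idx == 0L) 0 else unname(theta[idx])
}

# all fold-change values of one parameter as a length-n vector (reference = 0)
r_vector <- function(mcm, theta, pn) {
  vapply(seq_len(mcm$n), function(j) r_of(mcm, theta, pn, j), numeric(1))
}
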