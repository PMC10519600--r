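#' Penalty specification
#'
#' Defines the regularization \eqn{\lambda\,\nu(r)} added to \eqn{\chi^2}.
#' In `clustered` mode \eqn{\nu(r) = \sum_{i, j<k} |r_i^{(j)} - r_i^{(k)}|^q}
#' sums over all \eqn{n(n-1)/2} unordered cell-type pairs (including the
#' implicit reference with \eqn{r^{(1)} = 0}), which promotes clusters of
#' cell types sharing a parameter value and is symmetric under relabelling
#' the reference. In `standard` mode only deviations from the reference are
#' penalized, \eqn{\nu(r) = \sum_{i, j} |r_i^{(j)}|^q}, which cannot detect
#' shared mechanisms between non-reference cell types.
#'
#' Terms with \eqn{|\Delta| < \epsilon} are considered exactly zero;
#' derivative magnitudes at such points are evaluated at \eqn{\epsilon}
#' to avoid the \eqn{L_q} singularity.
#'
#' @param q pseudonorm exponent in (0, 1]; default 0.8.
#' @param lambda regularization strength (>= 0).
#' @param epsilon zero threshold; default 1e-10.
#' @param mode `"clustered"` or `"standard"`.
#' @param regularized character vector of specific parameter names to
#'   regularize; `NULL` (default) regularizes all of them.
#' @return an object of class `penalty_spec`.
#' @export
penalty_spec <- function(q = 0.8, lambda = 1, epsilon = 1e-10,
                         mode = c("clustered", "standard"),
                         regularized = NULL) {
  mode <- match.arg(mode)
  stopifnot(q > 0, q <= 1, lambda >= 0, epsilon > 0)
  structure(list(q = q, lambda = lambda, epsilon = epsilon, mode = mode,
                 regularized = regularized),
            class = "penalty_spec")
}

#' Pairwise penalty terms of a replicated model
#'
#' One row per penalized pair: in clustered mode all unordered cell-type
#' pairs `(j, k)` per regularized parameter; in standard mode only the pairs
#' involving the reference (equivalent to penalizing `|r^(j)|`).
#'
#' @inheritParams penalty_value
#' @return tibble with columns `parameter`, `j`, `k`, `col_j`, `col_k`
#'   (theta column indices, 0 for the reference).
#' @export
pair_terms <- function(mcm, spec) {
  pars <- spec$regularized %||% mcm$specific
  bad <- setdiff(pars, mcm$specific)
  if (length(bad)) {
    stop("regularized parameters must be specific: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(mcm$n, 2)
  out <- tidyr::expand_grid(
    parameter = pars,
    idx = seq_len(ncol(pairs))
  )
  out$j <- pairs[1, out$idx]
  out$k <- pairs[2, out$idx]
  out$idx <- NULL
  if (spec$mode == "standard") {
    out <- out[out$j == mcm$reference | out$k == mcm$reference, , drop = FALSE]
  }
  out$col_j <- mapply(function(pn, j) mcm$r_index[pn, j], out$parameter, out$j)
  out$col_k <- mapply(function(pn, k) mcm$r_index[pn, k], out$parameter, out$k)
  tibble::as_tibble(out)
}

# signed differences Delta = r^(j) - r^(k) for each pair row
pair_deltas <- function(mcm, theta, pairs) {
  rj <- ifelse(pairs$col_j == 0L, 0, theta[pmax(pairs$col_j, 1L)])
  rk <- ifelse(pairs$col_k == 0L, 0, theta[pmax(pairs$col_k, 1L)])
  unname(rj - rk)
}

#' Evaluate the penalty function
#'
#' @param mcm a [replicate_model()] object.
#' @param theta flat parameter vector.
#' @param spec a [penalty_spec()].
#' @return list with `value` (\eqn{\nu}, the penalty before multiplying by
#'   \eqn{\lambda}) and `terms`, a per-pair tibble with the signed
#'   differences and term values.
#' @export
penalty_value <- function(mcm, theta, spec) {
  check_theta(mcm, theta)
  pairs <- pair_terms(mcm, spec)
  delta <- pair_deltas(mcm, theta, pairs)
  term <- ifelse(abs(delta) < spec$epsilon, 0, abs(delta)^spec$q)
  pairs$delta <- delta
  pairs$term <- term
  list(value = sum(term), terms = pairs)
}

#' Penalty residual block
#'
#' One residual per pair term, \eqn{\rho_m = \sqrt{\lambda}\,|\Delta|^{q/2}},
#' so that \eqn{\sum_m \rho_m^2 = \lambda\,\nu(r)} reproduces the penalized
#' objective exactly. Jacobian rows carry \eqn{\partial\rho_m/\partial r}
#' with opposite signs on the two pair members; \eqn{|\Delta|} is clipped
#' below at \eqn{\epsilon} before exponentiation in the derivative.
#'
#' @inheritParams penalty_value
#' @return list with `res`, `J` (rows x theta), `tag = "penalty"`, and the
#'   pair table.
#' @export
penalty_residuals <- function(mcm, theta, spec) {
  pairs <- pair_terms(mcm, spec)
  m <- nrow(pairs)
  J <- matrix(0, m, length(mcm$theta_names),
              dimnames = list(NULL, mcm$theta_names))
  if (spec$lambda == 0 || m == 0L) {
    return(list(res = numeric(m), J = J, tag = "penalty", pairs = pairs))
  }
  delta <- pair_deltas(mcm, theta, pairs)
  ad <- abs(delta)
  on_manifold <- ad < spec$epsilon
  res <- ifelse(on_manifold, 0, sqrt(spec$lambda) * ad^(spec$q / 2))
  dr <- sqrt(spec$lambda) * (spec$q / 2) *
    pmax(ad, spec$epsilon)^(spec$q / 2 - 1) * sign(delta)
  for (i in seq_len(m)) {
    if (pairs$col_j[i] > 0L) J[i, pairs$col_j[i]] <- dr[i]
    if (pairs$col_k[i] > 0L) J[i, pairs$col_k[i]] <- -dr[i]
  }
  pairs$delta <- delta
  pairs$on_manifold <- on_manifold
  list(res = res, J = J, tag = "penalty", pairs = pairs)
}

#' Analytic gradient of the penalty function
#'
#' \eqn{[\nabla\nu]_l = \sum q\,|\Delta|^{q-1}\,\mathrm{sgn}(\Delta)} over
#' the pair terms incident to coordinate `l`, with \eqn{|\Delta|} replaced
#' by \eqn{\max(|\Delta|, \epsilon)} so the singular terms are evaluated at
#' \eqn{\epsilon} rather than at the singularity.
#'
#' @inheritParams penalty_value
#' @return named numeric gradient over all theta coordinates (zero for base
#'   parameters).
#' @export
penalty_gradient <- function(mcm, theta, spec) {
  check_theta(mcm, theta)
  pairs <- pair_terms(mcm, spec)
  g <- stats::setNames(numeric(length(mcm$theta_names)), mcm$theta_names)
  if (nrow(pairs) == 0L) return(g)
  delta <- pair_deltas(mcm, theta, pairs)
  slope <- spec$q * pmax(abs(delta), spec$epsilon)^(spec$q - 1) * sign(delta)
  for (i in seq_len(nrow(pairs))) {
    if (pairs$col_j[i] > 0L) g[pairs$col_j[i]] <- g[pairs$col_j[i]] + slope[i]
    if (pairs$col_k[i] > 0L) g[pairs$col_k[i]] <- g[pairs$col_k[i]] - slope[i]
  }
  g
}
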