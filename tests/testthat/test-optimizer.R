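test_that("truncate_step lands on the first sign change with scalar scaling", {
  mcm <- decay_mcm()
  spec <- penalty_spec(q = 0.8, lambda = 1, mode = "clustered")

  # crossing of r2 itself: 0.2 with step -0.5 -> factor 0.4
  th <- c(p = -1.5, r_p_2 = 0.2, r_p_3 = 0.9)
  step <- c(p = 0, r_p_2 = -0.5, r_p_3 = 0)
  tr <- truncate_step(mcm, th, step, spec)
  expect_equal(tr$t, 0.4)
  expect_equal(unname(th["r_p_2"] + tr$step["r_p_2"]), 0)

  # no crossing anywhere: step unchanged
  step2 <- c(p = 0, r_p_2 = 0.05, r_p_3 = 0.05)
  tr2 <- truncate_step(mcm, th, step2, spec)
  expect_equal(tr2$t, 1)
  expect_equal(tr2$step, step2)

  # difference crossing exactly at t = 1: full step, endpoint on manifold
  th3 <- c(p = -1.5, r_p_2 = 0.3, r_p_3 = 0.1)
  step3 <- c(p = 0, r_p_2 = -0.1, r_p_3 = 0.1)
  tr3 <- truncate_step(mcm, th3, step3, spec)
  expect_equal(tr3$t, 1)
  expect_true(3 %in% tr3$crossings) # the (2,3) pair row
})

test_that("merge_sensitivities replaces member columns by their common value", {
  J <- cbind(c(1, 3), c(9, 9), c(-2, 5))
  out <- merge_sensitivities(J, c(1, 3), rule = "mean")
  expect_equal(out[, 1], c(-0.5, 4))
  expect_equal(out[, 3], c(-0.5, 4))
  expect_equal(out[, 2], c(9, 9)) # untouched

  # cluster of three columns: all equal the joint mean, order invariant
  J3 <- matrix(rnorm(12), 3, 4)
  m1 <- merge_sensitivities(J3, c(1, 2, 4), rule = "mean")
  m2 <- merge_sensitivities(J3, c(4, 1, 2), rule = "mean")
  expect_equal(m1, m2)
  expect_equal(m1[, 1], rowMeans(J3[, c(1, 2, 4)]))

  mx <- merge_sensitivities(J, c(1, 3), rule = "max")
  expect_equal(mx[, 1], c(-2, 5)) # per-row entry with the largest magnitude
  z <- merge_sensitivities(J, c(1, 3), rule = "zero")
  expect_true(all(z[, c(1, 3)] == 0))

  Jr <- release_pair(J, 2, c(1, 3))
  expect_equal(Jr[2, c(1, 3)], c(0, 0))
  expect_equal(Jr[1, ], J[1, ])
})

test_that("unregularized optimization recovers the generating parameters", {
  mcm <- decay_mcm()
  dat <- toy_data_closed_form(seed = 21)
  fit <- optimize_regularized(mcm, dat, penalty_spec(lambda = 0))
  expect_s3_class(fit, "ct_fit")
  # within sampling error (sd of the estimates is a few hundredths)
  expect_lt(abs(fit$theta["p"] + 1.5), 0.15)
  expect_lt(abs(fit$theta["r_p_2"] - 0.2), 0.2)
  expect_lt(abs(fit$theta["r_p_3"] - 0.3), 0.2)
  # objective decomposition is consistent
  expect_equal(fit$objective, fit$chi2 + fit$penalty, tolerance = 1e-9)
  expect_equal(fit$penalty, 0)
})

test_that("very large lambda collapses all fold changes to zero", {
  mcm <- decay_mcm()
  dat <- toy_data_closed_form(seed = 22)
  f0 <- optimize_regularized(mcm, dat, penalty_spec(lambda = 0))
  fit <- optimize_regularized(mcm, dat, penalty_spec(q = 0.8, lambda = 1e6),
                              start = f0$theta)
  expect_lt(max(abs(fit$theta[c("r_p_2", "r_p_3")])), 1e-10)
  expect_true(all(fit$manifold$active))
  expect_true(all(fit$manifold$dominated))
})

test_that("accepted iterations never increase the objective", {
  mcm <- decay_mcm()
  dat <- toy_data_closed_form(seed = 23)
  set.seed(23)
  for (i in 1:20) {
    start <- c(p = rnorm(1, -1, 0.5), r_p_2 = rnorm(1, 0, 0.3),
               r_p_3 = rnorm(1, 0, 0.3))
    lam <- sample(c(0, 1, 30, 300), 1)
    fit <- optimize_regularized(mcm, dat, penalty_spec(q = 0.8, lambda = lam),
                                start = start,
                                control = fit_control(trace = TRUE))
    if (!is.null(fit$trace) && nrow(fit$trace) > 1) {
      expect_true(all(diff(fit$trace$objective) <= 1e-12))
    }
    expect_equal(fit$objective, fit$chi2 + fit$penalty, tolerance = 1e-8)
  }
})

test_that("L1 threshold for landing on the manifold matches the closed form", {
  # n = 2 cell types, reference decay rate known: single penalized fold
  # change r with q = 1. The optimum sits at r = 0 iff |d chi2/d r(0)| <=
  # lambda (soft-threshold condition for a pair with the reference).
  mcm <- decay_mcm(n = 2)
  sigma <- 10^-1.3
  set.seed(31)
  tt <- 0:10
  dat <- dplyr::bind_rows(
    tibble::tibble(time = tt, observable = "x_obs",
                   value = exp(-10^-1.5 * tt) + rnorm(11, sd = sigma),
                   sigma = sigma, cell_type = 1),
    tibble::tibble(time = tt, observable = "x_obs",
                   value = exp(-10^-1.4 * tt) + rnorm(11, sd = sigma),
                   sigma = sigma, cell_type = 2)
  )
  fixed <- c(p = -1.5)
  db <- data_residuals(mcm, c(p = -1.5, r_p_2 = 0), dat)
  g0 <- 2 * sum(db$J[, "r_p_2"] * db$res)
  lambda_star <- abs(g0)
  fit_above <- optimize_regularized(
    mcm, dat, penalty_spec(q = 1, lambda = 1.1 * lambda_star), fixed = fixed)
  expect_lt(abs(fit_above$theta["r_p_2"]), 1e-10)
  fit_below <- optimize_regularized(
    mcm, dat, penalty_spec(q = 1, lambda = 0.9 * lambda_star), fixed = fixed)
  expect_gt(abs(fit_below$theta["r_p_2"]), 1e-6)
})

test_that("release lets the optimizer leave a manifold the data rejects", {
  # start exactly on r = 0 with weak regularization: the data gradient
  # dominates, the pair is released, and the fit moves off the manifold
  mcm <- decay_mcm(n = 2)
  sigma <- 10^-1.3
  tt <- 0:10
  dat <- dplyr::bind_rows(
    tibble::tibble(time = tt, observable = "x_obs",
                   value = exp(-10^-1.5 * tt), sigma = sigma, cell_type = 1),
    tibble::tibble(time = tt, observable = "x_obs",
                   value = exp(-10^-1.2 * tt), sigma = sigma, cell_type = 2)
  )
  fit <- optimize_regularized(mcm, dat, penalty_spec(q = 1, lambda = 0.1),
                              start = c(p = -1.5, r_p_2 = 0),
                              fixed = c(p = -1.5))
  expect_gt(abs(fit$theta["r_p_2"]), 0.1)
})

test_that("the zero merge rule cannot move a nonzero cluster; the mean rule can", {
  mcm <- decay_mcm()
  dat <- toy_data_closed_form(seed = 25)
  start <- c(p = -1.5, r_p_2 = 0.25, r_p_3 = 0.25) # on the (2,3) manifold
  spec <- penalty_spec(q = 0.8, lambda = 1e6)
  stuck <- optimize_regularized(mcm, dat, spec, start = start,
                                fixed = c(p = -1.5),
                                control = fit_control(merge_rule = "zero"))
  expect_equal(unname(stuck$theta[c("r_p_2", "r_p_3")]), c(0.25, 0.25))
  moved <- optimize_regularized(mcm, dat, spec, start = start,
                                fixed = c(p = -1.5),
                                control = fit_control(merge_rule = "mean"))
  expect_lt(max(abs(moved$theta[c("r_p_2", "r_p_3")])), 1e-10)
})

test_that("optimality report distinguishes dominated from released pairs", {
  mcm <- decay_mcm()
  dat <- toy_data_closed_form(seed = 26)
  # lambda = 0 at the optimum: criteria 6.1/6.2 hold, 6.3 is vacuous
  f0 <- optimize_regularized(mcm, dat, penalty_spec(lambda = 0))
  opt <- check_optimality(mcm, f0$theta, dat, penalty_spec(lambda = 0))
  expect_true(opt$converged)
  expect_lt(opt$crit1, 1e-4)

  # on-manifold point under strong regularization: dominated everywhere
  th0 <- c(p = f0$theta[["p"]], r_p_2 = 0, r_p_3 = 0)
  opt_hi <- check_optimality(mcm, th0, dat, penalty_spec(q = 0.8, lambda = 1e6))
  expect_true(all(opt_hi$manifold$dominated))
  # same point with tiny lambda: the data slope wins, 6.3 fails
  opt_lo <- check_optimality(mcm, th0, dat, penalty_spec(q = 1, lambda = 1e-4))
  expect_false(all(opt_lo$manifold$dominated))
  expect_false(opt_lo$converged)
})

test_that("optimization is reference invariant on toy data", {
  mcm <- decay_mcm()
  dat <- toy_data_closed_form(seed = 27)
  f1 <- optimize_regularized(mcm, dat, penalty_spec(q = 0.8, lambda = 30))
  for (ref in 2:3) {
    mref <- decay_mcm(reference = ref)
    fref <- optimize_regularized(mref, dat, penalty_spec(q = 0.8, lambda = 30),
                                 start = relabel_reference(
                                   mcm, ref, default_theta(mcm))$theta)
    expect_equal(fref$objective, f1$objective, tolerance = 1e-6)
    # same expanded decay rates in every cell type
    for (j in 1:3) {
      expect_equal(expand_parameters(mref, fref$theta, j),
                   expand_parameters(mcm, f1$theta, j), tolerance = 1e-3)
    }
  }
})

test_that("standard errors reflect the curvature of the data term", {
  mcm <- decay_mcm()
  dat <- toy_data_closed_form(seed = 28)
  fit <- optimize_regularized(mcm, dat, penalty_spec(lambda = 0))
  se <- fit_standard_errors(mcm, fit$theta, dat)
  expect_true(all(se > 0))
  # the toy estimates have standard errors of a few hundredths
  expect_true(all(se < 0.2))
})
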