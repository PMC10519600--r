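test_that("standard-mode penalty reproduces the reference-dependence example", {
  # three cell types at log10 p = (0.5, 0.75, 1.0)
  mcm <- decay_mcm()
  th <- c(p = 0.5, r_p_2 = 0.25, r_p_3 = 0.5)
  spec <- penalty_spec(q = 0.8, mode = "standard")
  pv <- penalty_value(mcm, th, spec)
  expect_equal(sort(abs(pv$terms$delta)), c(0.25, 0.5))
  expect_equal(pv$value, 0.25^0.8 + 0.5^0.8)

  # same point with cell type 2 as reference: two terms of magnitude 0.25
  rl <- relabel_reference(mcm, 2, th)
  pv2 <- penalty_value(rl$model, rl$theta, spec)
  expect_equal(sort(abs(pv2$terms$delta)), c(0.25, 0.25))
  expect_equal(pv2$value, 2 * 0.25^0.8)
  expect_false(isTRUE(all.equal(pv$value, pv2$value)))
})

test_that("clustered penalty value sums all pairwise differences", {
  mcm <- decay_mcm()
  th <- c(p = 0.5, r_p_2 = 0.25, r_p_3 = 0.5)
  spec1 <- penalty_spec(q = 1, mode = "clustered")
  expect_equal(penalty_value(mcm, th, spec1)$value, 0.25 + 0.5 + 0.25)
  expect_equal(nrow(pair_terms(mcm, spec1)), 3L) # n(n-1)/2

  # zero at the all-equal point, in both modes
  th0 <- c(p = 0.5, r_p_2 = 0, r_p_3 = 0)
  expect_equal(penalty_value(mcm, th0, spec1)$value, 0)
  expect_equal(penalty_value(mcm, th0, penalty_spec(mode = "standard"))$value, 0)
})

test_that("clustered penalty is reference invariant, standard is not", {
  mcm <- decay_mcm()
  set.seed(7)
  for (i in 1:25) {
    th <- c(p = rnorm(1), r_p_2 = rnorm(1), r_p_3 = rnorm(1))
    v1 <- penalty_value(mcm, th, penalty_spec(q = 0.8, mode = "clustered"))$value
    for (ref in 2:3) {
      rl <- relabel_reference(mcm, ref, th)
      v2 <- penalty_value(rl$model, rl$theta,
                          penalty_spec(q = 0.8, mode = "clustered"))$value
      expect_equal(v1, v2, tolerance = 1e-12)
    }
  }
  # asymmetry of the standard mode on the worked example is shown above
})

test_that("squared penalty residuals reproduce lambda * nu exactly", {
  mcm <- decay_mcm()
  # worked case: q = 1, lambda = 4, Delta = 0.25 -> rho = 1
  spec <- penalty_spec(q = 1, lambda = 4, mode = "standard")
  th <- c(p = 0, r_p_2 = 0.25, r_p_3 = 0.25)
  pr <- penalty_residuals(mcm, th, spec)
  expect_equal(pr$res[1], 1)
  expect_equal(pr$res[1]^2, 4 * 0.25)

  set.seed(11)
  for (i in 1:100) {
    q <- sample(c(0.8, 1), 1)
    lam <- runif(1, 0, 50)
    mode <- sample(c("clustered", "standard"), 1)
    th <- c(p = 0, r_p_2 = rnorm(1), r_p_3 = rnorm(1))
    spec <- penalty_spec(q = q, lambda = lam, mode = mode)
    pr <- penalty_residuals(mcm, th, spec)
    pv <- penalty_value(mcm, th, spec)
    expect_equal(sum(pr$res^2), lam * pv$value, tolerance = 1e-10)
  }

  # lambda = 0: zero block, objective reduces to chi2
  pr0 <- penalty_residuals(mcm, th, penalty_spec(lambda = 0))
  expect_true(all(pr0$res == 0))
  expect_true(all(pr0$J == 0))
})

test_that("penalty gradient has the sign bookkeeping of incident pairs", {
  mcm <- decay_mcm()
  # q = 1, 0 < a < b: dnu/dr2 = +1 (vs reference) - 1 (vs r3) = 0
  th <- c(p = 0, r_p_2 = 0.2, r_p_3 = 0.5)
  g <- penalty_gradient(mcm, th, penalty_spec(q = 1, mode = "clustered"))
  expect_equal(unname(g["r_p_2"]), 0)
  expect_equal(unname(g["r_p_3"]), 2) # own term + pair term, both +1
  expect_equal(unname(g["p"]), 0)
})

test_that("penalty gradient matches finite differences away from manifolds", {
  mcm <- decay_mcm()
  set.seed(5)
  nu_of <- function(th, spec) penalty_value(mcm, th, spec)$value
  for (i in 1:30) {
    spec <- penalty_spec(q = sample(c(0.8, 1), 1),
                         mode = sample(c("clustered", "standard"), 1))
    repeat {
      th <- c(p = 0, r_p_2 = rnorm(1), r_p_3 = rnorm(1))
      d <- abs(c(th[2], th[3], th[2] - th[3]))
      if (all(d > 1e-3)) break
    }
    g <- penalty_gradient(mcm, th, spec)
    h <- 1e-7
    for (nm in c("r_p_2", "r_p_3")) {
      up <- th; up[nm] <- up[nm] + h
      dn <- th; dn[nm] <- dn[nm] - h
      fd <- (nu_of(up, spec) - nu_of(dn, spec)) / (2 * h)
      expect_equal(unname(g[nm]), fd, tolerance = 1e-5)
    }
  }
})

test_that("penalty is zero iff all differences are within epsilon, and monotone", {
  mcm <- decay_mcm()
  spec <- penalty_spec(q = 0.8, mode = "clustered")
  th_eps <- c(p = 0, r_p_2 = 1e-12, r_p_3 = -1e-12)
  expect_equal(penalty_value(mcm, th_eps, spec)$value, 0)
  th_not <- c(p = 0, r_p_2 = 1e-6, r_p_3 = 0)
  expect_gt(penalty_value(mcm, th_not, spec)$value, 0)

  # monotone in |Delta|: scaling all fold changes up never decreases nu
  set.seed(3)
  for (i in 1:20) {
    th <- c(p = 0, r_p_2 = rnorm(1), r_p_3 = rnorm(1))
    v1 <- penalty_value(mcm, th, spec)$value
    th2 <- th * c(1, 1.5, 1.5)
    v2 <- penalty_value(mcm, th2, spec)$value
    expect_gte(v2, v1)
  }
})

test_that("penalty_spec validates its fields", {
  expect_error(penalty_spec(q = 0), "q")
  expect_error(penalty_spec(q = 1.2), "q")
  expect_error(penalty_spec(lambda = -1), "lambda")
  expect_error(penalty_spec(epsilon = 0), "epsilon")
})
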