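# enumerate all set partitions of 1..n (small n), as lists of groups
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (g in seq_along(p)) {
      q <- p
      q[[g]] <- c(q[[g]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

clusters_from_partition <- function(partition, n, parameter = "p") {
  group <- integer(n)
  for (g in seq_along(partition)) group[partition[[g]]] <- g
  group <- match(group, unique(group))
  tibble::tibble(parameter = parameter, cell_type = seq_len(n),
                 group = group, zero = group == group[1])
}

test_that("extract_clusters merges values within epsilon transitively", {
  mcm <- decay_mcm()
  cl <- extract_clusters(mcm, c(p = -1.5, r_p_2 = 1e-12, r_p_3 = 0.3))
  expect_equal(cl$group, c(1L, 1L, 2L))
  expect_equal(cl$zero, c(TRUE, TRUE, FALSE))

  cl2 <- extract_clusters(mcm, c(p = -1.5, r_p_2 = 0.2999999999, r_p_3 = 0.3),
                          epsilon = 1e-9)
  expect_equal(cl2$group, c(1L, 2L, 2L))
  expect_equal(cl2$zero, c(TRUE, FALSE, FALSE))

  # near-transitivity: chained pairs below epsilon form one cluster even if
  # the extreme members differ by slightly more than epsilon
  mcm4 <- decay_mcm(n = 4)
  th <- c(p = -1.5, r_p_2 = 0.3, r_p_3 = 0.3 + 0.8e-10, r_p_4 = 0.3 + 1.6e-10)
  cl3 <- extract_clusters(mcm4, th)
  expect_equal(cl3$group, c(1L, 2L, 2L, 2L))
})

test_that("count_constraints implements the one/two degrees-of-freedom rule", {
  n <- 3
  # nonzero {2,3} cluster: one constraint
  cl_23 <- clusters_from_partition(list(1L, c(2L, 3L)), n)
  expect_equal(count_constraints(cl_23, n)$k, 1L)
  # r2 = r3 = 0: two constraints, not three
  cl_0 <- clusters_from_partition(list(c(1L, 2L, 3L)), n)
  expect_equal(count_constraints(cl_0, n)$k, 2L)
  # all singletons: none
  cl_s <- clusters_from_partition(list(1L, 2L, 3L), n)
  expect_equal(count_constraints(cl_s, n)$k, 0L)

  # identity: constraints + free fold changes = total fold changes, all
  # partitions up to n = 5
  for (n in 2:5) {
    for (p in set_partitions(n)) {
      cl <- clusters_from_partition(p, n)
      cc <- count_constraints(cl, n)
      expect_equal(cc$k + cc$m, n - 1L)
    }
  }
})

test_that("lrt_select applies the chi-squared threshold at alpha = 0.05", {
  n <- 3
  cl_23 <- clusters_from_partition(list(1L, c(2L, 3L)), n)
  cl_s <- clusters_from_partition(list(1L, 2L, 3L), n)
  chi2_full <- 10

  # constrained equal to full: D = 0, never rejected
  tab <- lrt_select(list(list(lambda = 1, clusters = cl_23, chi2 = 10)),
                    chi2_full, n)
  expect_equal(tab$D, 0)
  expect_false(tab$rejected)

  # k = 1: the 95% quantile of chi-squared with 1 dof is 3.841 (tabulated)
  just_below <- 10 + 3.841 / 2
  just_above <- 10 + 3.85 / 2
  tab2 <- lrt_select(list(
    list(lambda = 1, clusters = cl_23, chi2 = just_below),
    list(lambda = 2, clusters = cl_23, chi2 = just_above)
  ), chi2_full, n)
  expect_equal(tab2$rejected, c(FALSE, TRUE))
  expect_equal(tab2$selected, c(TRUE, FALSE))

  # unconstrained candidates accepted only at D ~ 0
  tab3 <- lrt_select(list(
    list(lambda = 1, clusters = cl_s, chi2 = 10 + 1e-9),
    list(lambda = 2, clusters = cl_s, chi2 = 12)
  ), chi2_full, n)
  expect_equal(tab3$rejected, c(FALSE, TRUE))

  expect_error(lrt_select(list(), chi2_full, n), "empty")
})

test_that("constrained refits tie clusters exactly and count free parameters", {
  mcm <- decay_mcm()
  dat <- toy_data_closed_form(seed = 31)
  n <- 3

  # all singletons: identical to the unconstrained fit
  full <- optimize_regularized(mcm, dat, penalty_spec(lambda = 0))
  cl_s <- clusters_from_partition(list(1L, 2L, 3L), n)
  refit_s <- constrained_refit(mcm, dat, cl_s, start = full$theta)
  expect_equal(refit_s$chi2, full$chi2, tolerance = 1e-6)

  # nonzero {2,3} cluster: one shared fold change, satisfied exactly
  cl_23 <- clusters_from_partition(list(1L, c(2L, 3L)), n)
  refit <- constrained_refit(mcm, dat, cl_23, start = full$theta)
  expect_identical(unname(refit$theta["r_p_2"]), unname(refit$theta["r_p_3"]))
  expect_gte(refit$chi2, full$chi2 - 1e-6)

  # fully shared model: no fold-change freedom left
  cl_0 <- clusters_from_partition(list(c(1L, 2L, 3L)), n)
  refit0 <- constrained_refit(mcm, dat, cl_0, start = full$theta)
  expect_equal(unname(refit0$theta[c("r_p_2", "r_p_3")]), c(0, 0))
  expect_gt(refit0$chi2, refit$chi2)
})

test_that("lambda_scan returns the unconstrained model for a zero-only grid", {
  mcm <- decay_mcm()
  dat <- toy_data_closed_form(seed = 32)
  scan <- lambda_scan(mcm, dat, penalty_spec(q = 0.8), lambdas = 0)
  expect_equal(nrow(scan$table), 1L)
  expect_equal(scan$table$D, 0)
  expect_true(scan$table$selected)
  expect_equal(scan$table$k, 0L)
})

test_that("lambda_scan records a parsimonious model and its path", {
  sc <- toy_scenario(seed = 3, free_reference = FALSE)
  dat <- simulate_scenario(sc)
  scan <- lambda_scan(sc$mcm, dat, penalty_spec(q = 0.8, mode = "clustered"),
                      lambdas = 10^seq(-1, 3, by = 0.5), fixed = sc$fixed)
  expect_s3_class(scan, "ct_scan")
  expect_false(is.na(scan$selected))
  expect_equal(nrow(scan$table), 9L)
  # D is zero at small lambda (no constraints) and grows to the collapsed model
  expect_equal(scan$table$D[1], 0)
  expect_gt(dplyr::last(scan$table$D), 0)
  # path table covers every fold change and difference at every lambda
  path <- regularization_path(scan)
  expect_equal(nrow(path), 9L * 5L) # 2 fold changes + 3 differences
  # selection is the largest non-rejected lambda
  sel <- scan$selected
  expect_false(scan$table$rejected[sel])
  if (sel < nrow(scan$table)) {
    expect_true(all(scan$table$rejected[(sel + 1):nrow(scan$table)]))
  }
})

test_that("warm started and cold started scans agree on the toy problem", {
  sc <- toy_scenario(seed = 5, free_reference = FALSE)
  dat <- simulate_scenario(sc)
  grid <- 10^seq(0, 3, by = 0.5)
  warm <- lambda_scan(sc$mcm, dat, penalty_spec(q = 0.8), lambdas = grid,
                      fixed = sc$fixed, warm_start = TRUE)
  cold <- lambda_scan(sc$mcm, dat, penalty_spec(q = 0.8), lambdas = grid,
                      fixed = sc$fixed, warm_start = FALSE)
  expect_equal(warm$table$k, cold$table$k)
  expect_equal(warm$table$D, cold$table$D, tolerance = 1e-3)
})
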