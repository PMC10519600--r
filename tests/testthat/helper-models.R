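# shared fixtures, built in code

decay_model <- function() {
  ode_model(
    states = "x",
    odes = list(x = ~ -p * x),
    observables = list(x_obs = ~x),
    parameters = c(p = -1),
    initials = list(x = 1)
  )
}

decay_mcm <- function(n = 3, reference = 1L) {
  replicate_model(decay_model(), n = n, specific = "p", reference = reference)
}

# closed-form toy dataset (no integrator involved), truth log10 p = -1.5,
# r = (0, 0.2, 0.3), sigma = 10^-1.3
toy_data_closed_form <- function(seed, times = 0:10, noiseless = FALSE) {
  sigma <- 10^-1.3
  logp <- c(-1.5, -1.3, -1.2)
  set.seed(seed)
  dplyr::bind_rows(lapply(1:3, function(j) {
    y <- exp(-10^logp[j] * times)
    tibble::tibble(
      time = times, observable = "x_obs",
      value = y + if (noiseless) 0 else stats::rnorm(length(times), sd = sigma),
      sigma = sigma, cell_type = j
    )
  }))
}

expect_tibble_names <- function(x, nms) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(nms %in% names(x)))
}
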