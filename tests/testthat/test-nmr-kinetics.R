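make_exact_trace <- function(k = 1e-3, n = 12, t_max = 3000,
                             signals = c("Fo", "Fm", "Fp")) {
  generate_trace(trace_spec(k, times = seq(0, t_max, length.out = n),
                            signals = signals, noise_sd = 0))
}

test_that("log_ratio_transform anchors at zero and linearises exponentials", {
  # constant signal and reference: no reaction, all zeros
  flat <- kinetic_trace(
    tibble::tibble(time_s = c(0, 10, 20), Fo = 2, TFA = 1), "Fo")
  expect_equal(log_ratio_transform(flat, "Fo")$y, c(0, 0, 0))

  # signal/reference ratio halving gives -ln 2
  halving <- kinetic_trace(
    tibble::tibble(time_s = c(0, 60), Fo = c(2, 1), TFA = 1), "Fo")
  expect_equal(log_ratio_transform(halving, "Fo")$y[2], -log(2))

  # exact exponential: y(t) = -k t, invariant to reference level
  tr <- make_exact_trace(k = 1e-3)
  y <- log_ratio_transform(tr, "Fm")
  expect_equal(y$y, -1e-3 * y$time_s, tolerance = 1e-12)

  expect_error(log_ratio_transform(tr, "Fx"),
               class = "enaminekin_invalid_data")
})

test_that("trace validation names offending rows", {
  bad <- tibble::tibble(time_s = c(0, 10, 20), Fo = c(2, -1, 1),
                        TFA = c(1, 1, 1))
  expect_error(kinetic_trace(bad, "Fo"), "row\\(s\\) 2",
               class = "enaminekin_invalid_data")
  unsorted <- tibble::tibble(time_s = c(0, 20, 10), Fo = 1, TFA = 1)
  expect_error(kinetic_trace(unsorted, "Fo"),
               class = "enaminekin_invalid_data")
})

test_that("fit_kobs is exact on noiseless traces and averages per signal", {
  fit <- fit_kobs(make_exact_trace(k = 1e-3))
  expect_equal(fit$k_obs, 1e-3, tolerance = 1e-12)
  expect_lt(fit$stderr, 1e-15)
  expect_equal(fit$k_obs, mean(fit$per_signal_k))
  expect_equal(fit$n_points, 12)
  expect_equal(unname(fit$r_squared), rep(1, 3), tolerance = 1e-12)

  # anchored mode agrees on clean data
  fit0 <- fit_kobs(make_exact_trace(k = 1e-3), intercept = "anchored")
  expect_equal(fit0$k_obs, 1e-3, tolerance = 1e-12)

  # dropping a signal just narrows the average
  two <- make_exact_trace(signals = c("Fo", "Fp"))
  fit2 <- fit_kobs(two)
  expect_equal(length(fit2$per_signal_k), 2)
  expect_equal(fit2$k_obs, 1e-3, tolerance = 1e-12)
})

test_that("fit_kobs is invariant to uniform rescaling of all integrals", {
  tr <- generate_trace(trace_spec(8.83e-4, noise_sd = 0.02, seed = 5))
  scaled <- tibble::as_tibble(tr)
  for (cl in c("Fo", "Fm", "Fp", "TFA")) scaled[[cl]] <- scaled[[cl]] * 137
  fit1 <- fit_kobs(tr)
  fit2 <- fit_kobs(kinetic_trace(scaled, c("Fo", "Fm", "Fp")))
  expect_equal(fit2$k_obs, fit1$k_obs, tolerance = 1e-12)
  expect_equal(fit2$stderr, fit1$stderr, tolerance = 1e-12)
})

test_that("estimator recovers the generating constant with <1% bias", {
  k_true <- 1e-3
  ks <- vapply(1:200, function(s) {
    fit_kobs(generate_trace(trace_spec(k_true, noise_sd = 0.02,
                                       seed = s)))$k_obs
  }, numeric(1))
  expect_lt(abs(mean(ks) / k_true - 1), 0.01)
})

test_that("degenerate traces are rejected or trimmed", {
  short <- kinetic_trace(tibble::tibble(time_s = c(0, 10), Fo = c(2, 1),
                                        TFA = 1), "Fo")
  expect_error(fit_kobs(short), class = "enaminekin_insufficient_data")

  # a collapsed reference point is excluded with a warning
  tr <- tibble::as_tibble(make_exact_trace())
  tr$TFA[6] <- 1e-12
  expect_warning(fit <- fit_kobs(kinetic_trace(tr, c("Fo", "Fm", "Fp"))),
                 "below the floor")
  expect_equal(fit$n_points, 11)
  expect_equal(fit$k_obs, 1e-3, tolerance = 1e-10)

  # growing signal: negative rate warning
  growing <- kinetic_trace(
    tibble::tibble(time_s = c(0, 10, 20), Fo = c(1, 2, 4), TFA = 1), "Fo")
  expect_warning(fit_kobs(growing), "negative fitted rate")
})

test_that("tidy and glance expose the fit in tabular form", {
  fit <- fit_kobs(make_exact_trace())
  td <- tidy(fit)
  expect_equal(td$signal, c("Fo", "Fm", "Fp"))
  g <- glance(fit)
  expect_equal(g$k_obs, 1e-3, tolerance = 1e-12)
  expect_equal(g$n_signals, 3)
})
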