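test_that("amplitude fraction reduces correctly in limiting cases", {
  # (near-)equal lifetimes: amplitude fraction equals the photon fraction
  th <- decay_params(0.3, 0.5, 2, 2 * (1 + 1e-9), PERIOD)
  expect_equal(amplitude_fraction(th), 0.3 / 0.8, tolerance = 1e-6)
  # no long component: amplitude fraction is 1
  th <- decay_params(0.4, 0, TAU_S, TAU_L, PERIOD)
  expect_equal(amplitude_fraction(th), 1)
  # both zero: undefined
  th <- decay_params(0, 0, TAU_S, TAU_L, PERIOD)
  expect_error(amplitude_fraction(th), "undefined")
})

test_that("amplitude fraction matches numeric integration of the component densities", {
  # full window, T >> tau: a_S/(1-a_S) -> (f_S/tau_S)/(f_L/tau_L)
  b <- flim_binning(4096, dt = 0.1)  # 409.6 ns window = period
  th <- decay_params(0.3, 0.6, TAU_S, TAU_L, T = 409.6)
  a <- amplitude_fraction(th, b)
  expect_equal(a / (1 - a), (0.3 / TAU_S) / (0.6 / TAU_L), tolerance = 1e-3)
  # against direct numeric integration on the actual masked window
  bm <- flim_binning(256, 10 / 256, mask = window_mask(256, 20, 230))
  th <- decay_params(0.25, 0.65, TAU_S, TAU_L, PERIOD)
  kappa <- vapply(c(TAU_S, TAU_L), function(tau) {
    e <- bin_edges(bm)
    sum(vapply(which(bm$mask), function(i)
      stats::integrate(function(t) exp(-t / tau), e$left[i], e$right[i],
                       rel.tol = 1e-12)$value, 0))
  }, 0)
  oracle <- (0.25 / kappa[1]) / (0.25 / kappa[1] + 0.65 / kappa[2])
  expect_equal(amplitude_fraction(th, bm), oracle, tolerance = 1e-8)
})

test_that("least squares recovers fractions exactly from noise-free counts", {
  th <- theta_ref(0.3, 0.6)
  p <- mixture_bin_probabilities(th, IRF, BIN)
  h <- flim_histogram(round(1e7 * p), BIN)
  ls <- least_squares_fractions(h, IRF, TAU_S, TAU_L, PERIOD)
  expect_lt(abs(ls$f_S - 0.3), 1e-6)
  expect_lt(abs(ls$f_L - 0.6), 1e-6)
})

test_that("flim_fit returns a coherent model object across methods", {
  th <- theta_ref()
  h <- simulate_histogram(th, IRF, BIN, 5000, seed = 41)
  fit <- flim_fit(h, IRF, TAU_S, TAU_L, PERIOD)
  expect_s3_class(fit, "flim_fit")
  expect_named(coef(fit), c("f_S", "f_L", "f_B"))
  expect_lt(abs(coef(fit)[["f_S"]] - 0.3), 0.05)
  # predicted probabilities are a distribution; counts scale by n
  expect_equal(sum(predict(fit, "prob")), 1, tolerance = 1e-10)
  expect_equal(sum(predict(fit, "counts")), h$n_photons, tolerance = 1e-6)
  # residuals: finite on recorded bins, centered near zero
  r <- residuals(fit)
  expect_true(all(is.finite(r[BIN$mask])))
  expect_lt(abs(mean(r[BIN$mask])), 0.5)
  # simulate from the fit is seed-reproducible
  s1 <- simulate(fit, nsim = 2, seed = 7)
  s2 <- simulate(fit, nsim = 2, seed = 7)
  expect_identical(lapply(s1, `[[`, "counts"), lapply(s2, `[[`, "counts"))
  expect_s3_class(logLik(fit), "logLik")
  expect_output(print(summary(fit)), "f_S")

  fit_mc <- flim_fit(h, IRF, TAU_S, TAU_L, PERIOD, method = "mcmc",
                     n_samples = 3000, seed = 2)
  expect_lt(abs(coef(fit_mc)[["f_S"]] - coef(fit)[["f_S"]]), 0.03)
  fit_ls <- flim_fit(h, IRF, TAU_S, TAU_L, PERIOD, method = "ls")
  expect_lt(abs(coef(fit_ls)[["f_S"]] - coef(fit)[["f_S"]]), 0.05)
})

test_that("fit report marginals integrate to one and intervals bracket the mean", {
  th <- theta_ref()
  h <- simulate_histogram(th, IRF, BIN, 3000, seed = 43)
  fit <- flim_fit(h, IRF)
  for (m in fit$marginals) expect_equal(sum(m$mass), 1, tolerance = 1e-10)
  est <- fit$estimates
  expect_true(all(est$lower <= est$mean & est$mean <= est$upper))
})
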