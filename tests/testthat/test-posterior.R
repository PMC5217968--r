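test_that("zero-photon posterior is the prior: uniform over the grid", {
  h <- flim_histogram(numeric(BIN$n_bins), BIN)
  g <- flim_grid(f_S = seq(0, 1, length.out = 21),
                 f_L = seq(0, 1, length.out = 21),
                 tau_S = TAU_S, tau_L = TAU_L, T = PERIOD)
  post <- grid_posterior(h, g, IRF)
  mass <- exp(post$log_density - post$log_norm)
  expect_lt(max(abs(mass - 1 / nrow(post$points))), 1e-12)
})

test_that("two-point posterior odds equal the likelihood ratio", {
  th <- theta_ref()
  h <- simulate_histogram(th, IRF, BIN, 1000, seed = 21)
  g <- flim_grid(f_S = c(0.2, 0.4), f_L = 0.6,
                 tau_S = TAU_S, tau_L = TAU_L, T = PERIOD)
  post <- grid_posterior(h, g, IRF)
  ll <- vapply(c(0.2, 0.4), function(fs)
    log_likelihood(h, decay_params(fs, 0.6, TAU_S, TAU_L, PERIOD), IRF), 0)
  mass <- exp(post$log_density - post$log_norm)
  expect_equal(log(mass[1] / mass[2]), ll[1] - ll[2], tolerance = 1e-10)
})

test_that("grid excludes points outside the fraction simplex", {
  g <- flim_grid(f_S = seq(0, 1, length.out = 11),
                 f_L = seq(0, 1, length.out = 11))
  expect_true(all(g$points$f_S + g$points$f_L <= 1 + 1e-12))
  expect_error(flim_grid(f_S = c(0.9, 0.95), f_L = c(0.2, 0.4)),
               "empty")
})

test_that("marginalization recovers factors of a separable density and conserves mass", {
  x <- seq(0, 1, length.out = 11)
  y <- seq(0, 1, length.out = 7)
  pts <- expand.grid(a = x, b = y)
  g_x <- dnorm(x, 0.4, 0.2)
  h_y <- exp(-2 * y)
  post <- structure(list(points = pts,
                         log_density = log(dnorm(pts$a, 0.4, 0.2)) +
                           log(exp(-2 * pts$b)),
                         log_norm = NA, axes = c("a", "b")),
                    class = "flim_posterior")
  post$log_norm <- flimbayes:::log_sum_exp(post$log_density)
  ma <- marginalize(post, "a")
  expect_lt(max(abs(ma$mass - g_x / sum(g_x))), 1e-12)
  expect_equal(sum(ma$mass), 1, tolerance = 1e-10)
  expect_equal(sum(marginalize(post, "b")$mass), 1, tolerance = 1e-10)
  expect_error(marginalize(post, "nope"), "unknown parameter")
})

test_that("mean and mode estimators follow the lattice arithmetic", {
  skewed <- structure(list(parameter = "f_S", values = c(0, 0.5, 1),
                           mass = c(0.5, 0.3, 0.2)),
                      class = "flim_marginal")
  expect_equal(post_estimate(skewed, "mean"), 0.35)
  expect_equal(post_estimate(skewed, "mode"), 0)
  # tie broken toward the smallest lattice value
  tied <- structure(list(parameter = "f_S", values = c(0.2, 0.4, 0.6),
                         mass = c(0.4, 0.2, 0.4)),
                    class = "flim_marginal")
  expect_equal(post_estimate(tied, "mode"), 0.2)
  sym <- structure(list(parameter = "f_S", values = c(0.1, 0.2, 0.3),
                        mass = c(0.25, 0.5, 0.25)),
                   class = "flim_marginal")
  expect_equal(post_estimate(sym, "mean"), 0.2)
  expect_equal(post_estimate(sym, "mode"), 0.2)
})

test_that("a skewed truncated posterior separates mode and mean", {
  # very low photon count near the f_S = 0 boundary
  th <- decay_params(0.05, 0.93, TAU_S, TAU_L, PERIOD)
  h <- simulate_histogram(th, IRF, BIN, 80, seed = 5)
  g <- flim_grid(tau_S = TAU_S, tau_L = TAU_L, T = PERIOD)
  mg <- marginalize(grid_posterior(h, g, IRF), "f_S")
  expect_gt(abs(post_estimate(mg, "mean") - post_estimate(mg, "mode")), 1e-3)
})

test_that("grid posterior recovers simulated fractions within posterior uncertainty", {
  th <- decay_params(0.5, 0.4, TAU_S, TAU_L, PERIOD)
  h <- simulate_histogram(th, IRF, BIN, 1e6, seed = 77)
  fit <- flim_fit(h, IRF, TAU_S, TAU_L, PERIOD)
  est <- fit$estimates
  m <- est[est$parameter == "f_S", ]
  expect_lt(abs(m$mean - 0.5), 3 * m$sd)
  m <- est[est$parameter == "f_L", ]
  expect_lt(abs(m$mean - 0.4), 3 * m$sd)
})

test_that("posterior-mean estimates are nearly unbiased with calibrated intervals", {
  # 50 simulated datasets at 1e5 photons, f_S = 0.3, f_L = 0.6
  th <- theta_ref(0.3, 0.6)
  engine <- flimbayes:::fraction_fitter(IRF, BIN, TAU_S, TAU_L, PERIOD)
  set.seed(314)
  est <- t(replicate(50, {
    h <- simulate_histogram(th, IRF, BIN, 1e5)
    e <- engine(h)$estimates
    r <- e[e$parameter == "f_S", ]
    c(r$mean, r$lower, r$upper)
  }))
  bias <- mean(est[, 1]) - 0.3
  coverage <- mean(est[, 2] <= 0.3 & 0.3 <= est[, 3])
  expect_lt(abs(bias), 0.01)
  expect_gte(coverage, 0.88)
  expect_lte(coverage, 0.99)
})

test_that("posterior width shrinks as photon counts grow by decades", {
  th <- theta_ref()
  engine <- flimbayes:::fraction_fitter(IRF, BIN, TAU_S, TAU_L, PERIOD)
  sds <- vapply(c(1e3, 1e4, 1e5, 1e6), function(n) {
    h <- simulate_histogram(th, IRF, BIN, n, seed = 99)
    e <- engine(h)$estimates
    e$sd[e$parameter == "f_S"]
  }, 0)
  expect_true(all(diff(sds) < 0))
})
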