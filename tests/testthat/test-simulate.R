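test_that("zero photons give an all-zero histogram", {
  h <- simulate_histogram(theta_ref(), IRF, BIN, 0, seed = 1)
  expect_true(all(h$counts == 0))
  expect_equal(h$n_photons, 0)
})

test_that("simulated histograms are seed-deterministic", {
  th <- theta_ref()
  h1 <- simulate_histogram(th, IRF, BIN, 10000, seed = 5)
  h2 <- simulate_histogram(th, IRF, BIN, 10000, seed = 5)
  expect_identical(h1$counts, h2$counts)
  t1 <- simulate_photons(th, IRF, BIN, 1000, seed = 5)
  t2 <- simulate_photons(th, IRF, BIN, 1000, seed = 5)
  expect_identical(t1, t2)
})

test_that("pure background sampling is uniform over recorded bins", {
  th <- decay_params(0, 0, TAU_S, TAU_L, PERIOD)
  h <- simulate_histogram(th, IRF, BIN, 1e6, seed = 11)
  gof <- chisq.test(h$counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("binned counts track the analytic bin probabilities", {
  th <- theta_ref(0.3, 0.6)
  n <- 1e7
  h <- simulate_histogram(th, IRF, BIN, n, seed = 13)
  p <- mixture_bin_probabilities(th, IRF, BIN)
  z <- abs(h$counts / n - p) / sqrt(pmax(p * (1 - p) / n, 1e-300))
  expect_lt(max(z[BIN$mask]), 5)
})

test_that("photon arrival times have the exponential mean in the wide-window limit", {
  tau <- 0.2
  b <- flim_binning(500, dt = 0.02)  # 10 ns window
  th <- decay_params(1, 0, tau, 100, T = 10)  # T/tau = 50, window = period
  tt <- simulate_photons(th, delta_irf(b, 1), b, 50000, seed = 17)
  se <- tau / sqrt(50000)
  expect_lt(abs(mean(tt) - tau), 3 * se + 0.02 / 2)  # half-bin IRF offset slack
  expect_true(all(tt >= 0 & tt < 10))
})

test_that("per-photon and binned simulators agree in distribution", {
  th <- theta_ref()
  h1 <- simulate_histogram(th, IRF, BIN, 1e6, seed = 5)
  h2 <- bin_photons(simulate_photons(th, IRF, BIN, 1e6, seed = 6), BIN)
  expect_equal(h2$n_photons, 1e6)
  keep <- h1$counts + h2$counts > 0
  p <- suppressWarnings(
    chisq.test(rbind(h1$counts[keep], h2$counts[keep]))$p.value)
  expect_gt(p, 0.01)
})

test_that("master subsampling follows multinomial moments", {
  b <- tiny_binning(8)
  th <- decay_params(0.6, 0.35, TAU_S, TAU_L, PERIOD)
  m <- master_curve(th, delta_irf(b, 1), b, n_effective = 1e6)
  set.seed(23)
  draws <- replicate(1000, subsample_master(m, 100)$counts)
  expected <- 100 * m$counts / m$total
  se <- sqrt(100 * (m$counts / m$total) * (1 - m$counts / m$total) / 1000)
  expect_true(all(abs(rowMeans(draws) - expected) <= 4 * se + 1e-9))
  # single-bin master puts everything in that bin
  m1 <- structure(list(counts = c(0, 5, 0, 0, 0, 0, 0, 0), binning = b,
                       theta = th, irf = delta_irf(b, 1), label = "x",
                       total = 5), class = "flim_master")
  expect_equal(subsample_master(m1, 50, seed = 2)$counts[2], 50)
  # determinism
  expect_identical(subsample_master(m, 500, seed = 3)$counts,
                   subsample_master(m, 500, seed = 3)$counts)
})

test_that("mixing masters draws the prescribed short-photon count", {
  b <- tiny_binning(8)
  th <- decay_params(0.5, 0.45, TAU_S, TAU_L, PERIOD)
  # masters with disjoint support so the split is observable
  short <- structure(list(counts = c(1, 1, 0, 0, 0, 0, 0, 0) * 1e6,
                          binning = b, theta = th, irf = delta_irf(b, 1),
                          label = "short-only", total = 2e6),
                     class = "flim_master")
  long <- structure(list(counts = c(0, 0, 0, 0, 0, 0, 1, 1) * 1e6,
                         binning = b, theta = th, irf = delta_irf(b, 1),
                         label = "long-only", total = 2e6),
                    class = "flim_master")
  h <- mix_masters(short, long, 2^-7, 5e7, seed = 4)
  expect_equal(sum(h$counts[1:2]), floor(2^-7 * 5e7 + 0.5))
  expect_equal(h$n_photons, 5e7)
  h0 <- mix_masters(short, long, 0, 1000, seed = 5)
  expect_equal(sum(h0$counts[1:2]), 0)
  expect_error(mix_masters(short, long, 1.5, 100), "invalid parameter")
})
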