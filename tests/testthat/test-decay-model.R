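test_that("decay parameter validation enforces the simplex and lifetime order", {
  th <- decay_params(0.3, 0.6, 0.48, 4.03)
  expect_equal(th$f_S + th$f_L + th$f_B, 1, tolerance = 1e-12)
  expect_error(decay_params(0.7, 0.5, 0.48, 4.03), "exceeds 1")
  expect_error(decay_params(0.3, 0.6, 4.03, 0.48), "ordering")
  expect_error(decay_params(-0.1, 0.6, 0.48, 4.03), "\\[0, 1\\]")
  expect_error(decay_params(0.3, 0.6, 0.48, 4.03, T = -1), "positive")
})

test_that("periodic decay density matches the truncated pulse-train sum", {
  e <- bin_edges(BIN)
  for (tau in c(0.1, 0.453, 0.48, 3.921, 4.03, 10)) {
    oracle <- rowSums(vapply(0:50, function(k)
      exp(-(e$left + k * PERIOD) / tau) - exp(-(e$right + k * PERIOD) / tau),
      numeric(BIN$n_bins)))
    oracle <- oracle / sum(oracle)
    expect_lt(max(abs(oracle - periodic_decay_density(tau, PERIOD, BIN))),
              1e-10)
  }
})

test_that("infinite-lifetime limit of the decay density is uniform", {
  p <- periodic_decay_density(1e9, PERIOD, BIN)
  expect_lt(max(abs(p - 1 / BIN$n_bins)), 1e-6)
  # and on a masked grid, uniform over the masked-in bins only
  b <- flim_binning(64, 0.1, mask = window_mask(64, 10, 50))
  p <- periodic_decay_density(1e9, PERIOD, b)
  expect_lt(max(abs(p[b$mask] - 1 / 41)), 1e-6)
  expect_true(all(p[!b$mask] == 0))
})

test_that("periodic prefactor is absorbed by normalization", {
  e <- bin_edges(BIN)
  for (tau in c(0.48, 4.03)) {
    raw <- exp(-e$left / tau) - exp(-e$right / tau)
    pref <- 1 / (1 - exp(-PERIOD / tau))
    expect_equal(raw * pref / sum(raw * pref), raw / sum(raw),
                 tolerance = 1e-12)
    expect_lt(max(abs(raw * pref / sum(raw * pref) -
                        periodic_decay_density(tau, PERIOD, BIN))), 1e-12)
  }
})

test_that("reference dye lifetimes give valid normalized probabilities", {
  for (tau in c(0.453, 3.921)) {
    p <- periodic_decay_density(tau, PERIOD, BIN)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("IRF convolution has delta identity and shift properties", {
  p <- periodic_decay_density(0.48, PERIOD, BIN)
  out <- convolve_irf(p, delta_irf(BIN, 1), BIN)
  expect_lt(max(abs(out - p)), 1e-12)
  k <- 17
  shifted <- convolve_irf(p, delta_irf(BIN, k), BIN)
  manual <- p[((seq_len(BIN$n_bins) - 1 - (k - 1)) %% BIN$n_bins) + 1]
  expect_lt(max(abs(shifted - manual / sum(manual))), 1e-12)
})

test_that("IRF convolution matches the O(n^2) double-sum oracle", {
  p <- periodic_decay_density(0.48, PERIOD, BIN)
  irf <- gaussian_irf(BIN, center = 0.5, sigma = 2 * BIN$dt)
  n <- BIN$n_bins
  oracle <- numeric(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      oracle[i] <- oracle[i] + p[j] * irf$weights[((i - j) %% n) + 1]
  oracle <- oracle / sum(oracle)
  expect_lt(max(abs(convolve_irf(p, irf, BIN) - oracle)), 1e-12)
})

test_that("convolution rejects mismatched grids", {
  p <- periodic_decay_density(0.48, PERIOD, BIN)
  b2 <- flim_binning(128, 10 / 128)
  expect_error(convolve_irf(p, delta_irf(b2, 1), BIN), "different grids")
})

test_that("mixture probabilities reduce to components and weight exactly", {
  # pure background is uniform
  th_b <- decay_params(0, 0, TAU_S, TAU_L, PERIOD)
  p <- mixture_bin_probabilities(th_b, IRF, BIN)
  expect_lt(max(abs(p - 1 / BIN$n_bins)), 1e-14)
  # single component with delta IRF equals the bare periodic density
  th_s <- decay_params(1, 0, TAU_S, TAU_L, PERIOD)
  p <- mixture_bin_probabilities(th_s, delta_irf(BIN, 1), BIN)
  expect_lt(max(abs(p - periodic_decay_density(TAU_S, PERIOD, BIN))), 1e-12)
  # weighted sum of separately computed components
  th <- decay_params(0.3, 0.6, 0.48, 4.03, 12.5)
  ps <- component_density(0.48, 12.5, IRF, BIN)
  pl <- component_density(4.03, 12.5, IRF, BIN)
  u <- rep(1 / BIN$n_bins, BIN$n_bins)
  expect_lt(max(abs(mixture_bin_probabilities(th, IRF, BIN) -
                      (0.3 * ps + 0.6 * pl + 0.1 * u))), 1e-12)
})

test_that("bin probabilities are normalized for randomized parameters", {
  set.seed(42)
  for (i in 1:100) {
    f_s <- runif(1)
    f_l <- runif(1, 0, 1 - f_s)
    tau_s <- runif(1, 0.05, 2)
    tau_l <- tau_s + runif(1, 0.1, 8)
    th <- decay_params(f_s, f_l, tau_s, tau_l, PERIOD)
    p <- mixture_bin_probabilities(th, IRF, BIN)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-10)
  }
})

test_that("delta-IRF full-mask density matches the non-periodic integral when T >> tau", {
  tau <- 0.2
  T_big <- 50 * tau
  b <- flim_binning(64, dt = 0.1)
  e <- bin_edges(b)
  oracle <- exp(-e$left / tau) - exp(-e$right / tau)
  oracle <- oracle / sum(oracle)
  p <- component_density(tau, T_big, delta_irf(b, 1), b)
  expect_lt(max(abs(p - oracle)), 1e-8)
})

test_that("bin-mask removal renormalizes and matches the conditional multinomial", {
  p <- periodic_decay_density(0.48, PERIOD, BIN)
  expect_identical(apply_bin_mask(p, rep(TRUE, BIN$n_bins)), p)
  # removing mass q scales retained bins by 1/(1-q)
  mask <- seq_len(BIN$n_bins) > 16
  q <- sum(p[!mask])
  pm <- apply_bin_mask(p, mask)
  expect_lt(max(abs(pm[mask] - p[mask] / (1 - q))), 1e-12)
  expect_error(apply_bin_mask(p, rep(FALSE, BIN$n_bins)), "degenerate")
  # likelihood of a masked single-component histogram equals the
  # conditional-distribution oracle
  th <- decay_params(1, 0, TAU_S, TAU_L, PERIOD)
  h <- simulate_histogram(th, IRF, BIN, 5000, seed = 31)
  hm <- mask_histogram(h, mask)
  bm <- hm$binning
  ll <- log_likelihood(hm, th, flim_irf(IRF$weights, bm))
  p_full <- mixture_bin_probabilities(th, IRF, BIN)
  p_cond <- p_full[mask] / sum(p_full[mask])
  oracle <- sum(h$counts[mask] * log(p_cond))
  expect_lt(abs(ll - oracle), 1e-10)
})
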