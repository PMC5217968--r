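#' Convert photon fractions to amplitude fractions
#'
#' Least-squares decay fitting reports the pre-exponential amplitudes of
#' the biexponential, while the mixture model works in photon-count
#' fractions.  The photon count collected from component `j` inside the
#' recorded window is proportional to `a_j * kappa_j` with
#' `kappa_j = integral of exp(-t/tau_j)` over the masked-in window (for a
#' full period this is `tau_j * (1 - exp(-T/tau_j))`), so the short-
#' lifetime amplitude fraction is
#' `a_S = (f_S/kappa_S) / (f_S/kappa_S + f_L/kappa_L)`.
#'
#' @param theta a [decay_params()] with `f_S + f_L > 0`.
#' @param binning optional [flim_binning()]; when supplied, `kappa` is the
#'   integral over the masked-in bins only, otherwise over the full period.
#' @return the short-lifetime amplitude fraction `a_S`; the long-lifetime
#'   amplitude fraction is `1 - a_S`.
#' @examples
#' th <- decay_params(0.5, 0.5, 0.48, 4.03)
#' amplitude_fraction(th)
#' @export
amplitude_fraction <- function(theta, binning = NULL) {
  stopifnot(inherits(theta, "decay_params"))
  if (theta$f_S + theta$f_L <= 0)
    stop("undefined amplitude ratio: both photon fractions are zero",
         call. = FALSE)
  kap <- function(tau) {
    if (is.null(binning)) return(tau * (1 - exp(-theta$T / tau)))
    e <- bin_edges(binning)
    m <- binning$mask
    tau * sum(exp(-e$left[m] / tau) - exp(-e$right[m] / tau))
  }
  as <- theta$f_S / kap(theta$tau_S)
  al <- theta$f_L / kap(theta$tau_L)
  as / (as + al)
}

#' Least-squares fraction estimate (baseline method)
#'
#' Weighted nonlinear least squares on the model counts, the conventional
#' alternative to the posterior: minimizes
#' `sum_i (P_i - n * p_i(theta))^2 / max(P_i, 1)` over the two free
#' fractions with the lifetimes fixed.  The simplex constraint is handled
#' by the smooth reparametrization `f_S = q * r`, `f_L = q * (1 - r)` with
#' `q, r` in `[0, 1]`, optimized by L-BFGS-B from the best point of a
#' coarse scan.
#'
#' @param hist a [flim_histogram()].
#' @param irf a [flim_irf()] on the same binning.
#' @param tau_S,tau_L fixed lifetimes, ns.
#' @param period excitation period, ns.
#' @return list with `f_S`, `f_L`, `f_B`, `amp_short`, `amp_long` (the
#'   amplitude fractions), `objective` and the optimizer's convergence
#'   code.
#' @export
least_squares_fractions <- function(hist, irf, tau_S = 0.48, tau_L = 4.03,
                                    period = 12.5) {
  stopifnot(inherits(hist, "flim_histogram"))
  b <- hist$binning
  m <- b$mask
  counts <- hist$counts[m]
  n <- sum(counts)
  p_s <- component_density(tau_S, period, irf, b)[m]
  p_l <- component_density(tau_L, period, irf, b)[m]
  u <- uniform_background(b)[m]
  wts <- 1 / pmax(counts, 1)
  obj <- function(par) {
    f_s <- par[1] * par[2]
    f_l <- par[1] * (1 - par[2])
    p <- f_s * p_s + f_l * p_l + (1 - f_s - f_l) * u
    sum(wts * (counts - n * p)^2)
  }
  scan <- expand.grid(q = seq(0.05, 1, by = 0.1), r = seq(0.05, 0.95, by = 0.1))
  start <- unlist(scan[which.min(apply(scan, 1, obj)), ])
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(1, 1),
                      control = list(factr = 1e4, maxit = 500))
  if (fit$convergence != 0)
    stop(sprintf("least-squares fit did not converge (code %d: %s)",
                 fit$convergence, fit$message), call. = FALSE)
  f_s <- fit$par[1] * fit$par[2]
  f_l <- fit$par[1] * (1 - fit$par[2])
  th <- decay_params(f_s, f_l, tau_S, tau_L, period)
  a_s <- if (f_s + f_l > 0) amplitude_fraction(th, b) else NA_real_
  list(f_S = f_s, f_L = f_l, f_B = th$f_B,
       amp_short = a_s, amp_long = 1 - a_s,
       objective = fit$value, convergence = fit$convergence)
}

#' Fit the biexponential mixture model to a photon arrival histogram
#'
#' The main fitting interface.  With `method = "grid"` (default) the
#' posterior over the photon fractions `(f_S, f_L)` is evaluated on dense
#' uniform lattices under the uniform simplex prior, adaptively refined
#' until the lattice spacing resolves the posterior width, and marginal
#' means/modes/s.d./credible intervals are reported.  `method = "mcmc"`
#' samples the same posterior by random-walk Metropolis (and can free the
#' lifetimes as well); `method = "ls"` gives the weighted least-squares
#' point estimate.
#'
#' @param hist a [flim_histogram()].
#' @param irf a [flim_irf()] on the same binning.
#' @param tau_S,tau_L fixed lifetimes in ns (defaults: the reference-dye
#'   values 0.48 and 4.03 ns).
#' @param period excitation period in ns (12.5 ns for an 80 MHz laser).
#' @param method `"grid"`, `"mcmc"` or `"ls"`.
#' @param n_grid coarse lattice points per fraction axis (grid method).
#' @param adaptive refine the lattice until the spacing is below a tenth
#'   of the posterior s.d. on each axis (grid method).  With
#'   `adaptive = FALSE` a single pass on the coarse lattice is used.
#' @param free,n_samples,seed MCMC settings, see [mcmc_posterior()].
#' @param ... further arguments passed to [mcmc_posterior()].
#' @return An object of class `"flim_fit"` with `print()`, `summary()`,
#'   `coef()`, `predict()`, `residuals()`, `simulate()`, `plot()` and
#'   `logLik()` methods.  `estimates` is a data frame with one row per
#'   reported parameter (`f_S`, `f_L`, `f_B`): posterior mean, mode, s.d.
#'   and 95% credible bounds.
#' @examples
#' b <- flim_binning(256, 10 / 256)
#' irf <- gaussian_irf(b)
#' th <- decay_params(0.3, 0.6, 0.48, 4.03)
#' h <- simulate_histogram(th, irf, b, n_photons = 2000, seed = 7)
#' fit <- flim_fit(h, irf)
#' coef(fit)
#' @export
flim_fit <- function(hist, irf, tau_S = 0.48, tau_L = 4.03, period = 12.5,
                     method = c("grid", "mcmc", "ls"),
                     n_grid = 201, adaptive = TRUE,
                     free = c("f_S", "f_L"), n_samples = 20000, seed = 1,
                     ...) {
  stopifnot(inherits(hist, "flim_histogram"))
  method <- match.arg(method)
  b <- hist$binning
  cl <- match.call()
  if (method == "grid") {
    engine <- fraction_fitter(irf, b, tau_S, tau_L, period,
                              n_coarse = n_grid,
                              max_stages = if (adaptive) 8 else 1)
    res <- engine(hist)
    est <- res$estimates
    # background row, derived from the joint posterior
    pts <- res$posterior$points
    mass <- exp(res$posterior$log_density - res$posterior$log_norm)
    mb <- structure_marginal(pmax(0, 1 - pts$f_S - pts$f_L), mass, "f_B")
    cib <- credible_interval(mb)
    est <- rbind(est, data.frame(parameter = "f_B",
                                 mean = post_estimate(mb, "mean"),
                                 mode = post_estimate(mb, "mode"),
                                 sd = marginal_sd(mb),
                                 lower = cib[["lower"]],
                                 upper = cib[["upper"]]))
    marginals <- c(res$marginals, list(f_B = mb))
    extra <- list(posterior = res$posterior, stages = res$stages)
  } else if (method == "mcmc") {
    mc <- mcmc_posterior(hist, irf, free = free,
                         fixed = list(tau_S = tau_S, tau_L = tau_L,
                                      T = period)[setdiff(
                                        c("tau_S", "tau_L", "T"), free)],
                         n_samples = n_samples, seed = seed, ...)
    s <- mc$samples
    marginals <- lapply(colnames(s), function(nm) {
      # lattice the samples for a mode/marginal on the same footing as grid
      br <- seq(min(s[, nm]) - 1e-9, max(s[, nm]) + 1e-9, length.out = 202)
      mid <- (br[-1] + br[-202]) / 2
      cnt <- tabulate(findInterval(s[, nm], br), nbins = 201)
      structure(list(parameter = nm, values = mid, mass = cnt / sum(cnt)),
                class = "flim_marginal")
    })
    names(marginals) <- colnames(s)
    est <- do.call(rbind, lapply(colnames(s), function(nm) {
      q <- unname(stats::quantile(s[, nm], c(0.025, 0.975)))
      data.frame(parameter = nm, mean = mean(s[, nm]),
                 mode = post_estimate(marginals[[nm]], "mode"),
                 sd = stats::sd(s[, nm]), lower = q[1], upper = q[2])
    }))
    if (all(c("f_S", "f_L") %in% colnames(s))) {
      fb <- 1 - s[, "f_S"] - s[, "f_L"]
      q <- unname(stats::quantile(fb, c(0.025, 0.975)))
      est <- rbind(est, data.frame(parameter = "f_B", mean = mean(fb),
                                   mode = NA_real_, sd = stats::sd(fb),
                                   lower = q[1], upper = q[2]))
    }
    extra <- list(mcmc = mc)
  } else {
    ls <- least_squares_fractions(hist, irf, tau_S, tau_L, period)
    est <- data.frame(parameter = c("f_S", "f_L", "f_B"),
                      mean = c(ls$f_S, ls$f_L, ls$f_B),
                      mode = NA_real_, sd = NA_real_,
                      lower = NA_real_, upper = NA_real_)
    marginals <- list()
    extra <- list(ls = ls)
  }
  get_est <- function(nm) est$mean[est$parameter == nm]
  f_s <- min(max(get_est("f_S"), 0), 1)
  f_l <- min(max(get_est("f_L"), 0), 1 - f_s)
  theta_hat <- decay_params(f_s, f_l, tau_S, tau_L, period)
  structure(c(list(call = cl, method = method, estimates = est,
                   marginals = marginals, theta_hat = theta_hat,
                   hist = hist, irf = irf,
                   settings = list(tau_S = tau_S, tau_L = tau_L,
                                   period = period, n_grid = n_grid,
                                   adaptive = adaptive)),
              extra),
            class = "flim_fit")
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf("FLIM mixture fit (%s), %s photons\n", x$method,
              format(x$hist$n_photons, big.mark = ",")))
  cat(sprintf("  f_S = %.4f, f_L = %.4f, f_B = %.4f  (tau_S = %.3g ns, tau_L = %.3g ns fixed)\n",
              x$theta_hat$f_S, x$theta_hat$f_L, x$theta_hat$f_B,
              x$settings$tau_S, x$settings$tau_L))
  invisible(x)
}

#' @export
summary.flim_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.flim_fit")
}

#' @export
print.summary.flim_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  est <- f$estimates
  est[-1] <- lapply(est[-1], signif, 5)
  print(est, row.names = FALSE)
  ll <- logLik(f)
  cat(sprintf("log-likelihood (up to multinomial constant): %.4f\n", ll))
  invisible(x)
}

#' @export
coef.flim_fit <- function(object, ...) {
  est <- object$estimates
  stats::setNames(est$mean, est$parameter)
}

#' @export
logLik.flim_fit <- function(object, ...) {
  val <- log_likelihood(object$hist, object$theta_hat, object$irf)
  structure(val, df = 2L, nobs = object$hist$n_photons, class = "logLik")
}

#' @export
predict.flim_fit <- function(object, type = c("prob", "counts"), ...) {
  type <- match.arg(type)
  p <- mixture_bin_probabilities(object$theta_hat, object$irf,
                                 object$hist$binning)
  if (type == "prob") p else p * object$hist$n_photons
}

#' @export
residuals.flim_fit <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  b <- object$hist$binning
  expd <- predict(object, "counts")
  r <- object$hist$counts - expd
  if (type == "pearson") r <- r / sqrt(pmax(expd, .PROB_FLOOR))
  r[!b$mask] <- NA_real_
  r
}

#' @export
simulate.flim_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(nsim), function(i)
    simulate_histogram(object$theta_hat, object$irf, object$hist$binning,
                       object$hist$n_photons))
}

#' @export
plot.flim_fit <- function(x, which = 1, ...) {
  b <- x$hist$binning
  t <- bin_times(b) + b$dt / 2
  m <- b$mask
  if (1 %in% which) {
    obs <- x$hist$counts[m]
    expd <- predict(x, "counts")[m]
    graphics::plot(t[m], pmax(obs, 0.5), log = "y", pch = 16, cex = 0.4,
                   xlab = "arrival time (ns)", ylab = "photon counts",
                   main = "arrival histogram and fitted model", ...)
    graphics::lines(t[m], pmax(expd, 0.5), col = "red3", lwd = 2)
  }
  if (2 %in% which && length(x$marginals)) {
    mg <- x$marginals[["f_S"]]
    graphics::plot(mg$values, mg$mass, type = "h",
                   xlab = "f_S", ylab = "posterior mass",
                   main = "marginal posterior of f_S")
  }
  invisible(x)
}
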