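#' MCMC sampling of the posterior
#'
#' Random-walk Metropolis sampler over a chosen subset of the model
#' parameters under the same likelihood and uniform priors as
#' [grid_posterior()].  Proposals are independent Gaussians per coordinate,
#' reflected at the box bounds (which keeps the proposal symmetric);
#' moves violating the simplex constraint `f_S + f_L <= 1` or the lifetime
#' ordering `tau_S < tau_L` have zero prior and are rejected.  The
#' per-coordinate proposal scales are auto-tuned during burn-in (20% of
#' the total chain by default) toward an acceptance rate between 20% and
#' 50%, then frozen.
#'
#' @param hist a [flim_histogram()].
#' @param irf a [flim_irf()] on the same binning.
#' @param free character vector of free parameter names, a subset of
#'   `c("f_S", "f_L", "tau_S", "tau_L")`.
#' @param fixed named list of the remaining parameter values (must include
#'   `T`; defaults `tau_S = 0.48`, `tau_L = 4.03`, `T = 12.5` are filled
#'   in for anything not free and not given).
#' @param bounds named list of `c(lo, hi)` per free parameter.  Defaults:
#'   `[0, 1]` for fractions, `[0.01, 20]` ns for lifetimes.
#' @param n_samples number of post-burn-in samples to return.
#' @param seed integer seed; the sample set is fully determined by it.
#' @param burn_frac fraction of the total chain discarded as burn-in.
#' @param init optional named numeric vector of starting values.
#' @return An object of class `"flim_mcmc"`: `samples` (matrix
#'   `n_samples` x `length(free)`), `acceptance`, `scales`, `seed`.
#' @export
mcmc_posterior <- function(hist, irf, free = c("f_S", "f_L"),
                           fixed = list(), bounds = list(),
                           n_samples = 10000, seed = 1,
                           burn_frac = 0.2, init = NULL) {
  stopifnot(inherits(hist, "flim_histogram"))
  all_names <- c("f_S", "f_L", "tau_S", "tau_L")
  free <- match.arg(free, all_names, several.ok = TRUE)
  if (n_samples < 1) stop("'n_samples' must be positive", call. = FALSE)
  defaults <- list(f_S = 0.3, f_L = 0.6, tau_S = 0.48, tau_L = 4.03, T = 12.5)
  fixed <- utils::modifyList(defaults[setdiff(names(defaults), free)], fixed)
  def_bounds <- list(f_S = c(0, 1), f_L = c(0, 1),
                     tau_S = c(0.01, 20), tau_L = c(0.01, 20))
  bounds <- utils::modifyList(def_bounds[free], bounds)

  b <- hist$binning
  counts <- hist$counts[b$mask]
  u <- uniform_background(b)[b$mask]
  taus_free <- any(c("tau_S", "tau_L") %in% free)
  if (!taus_free) {
    p_s <- component_density(fixed$tau_S, fixed$T, irf, b)[b$mask]
    p_l <- component_density(fixed$tau_L, fixed$T, irf, b)[b$mask]
  }
  log_post <- function(x) {
    par <- c(as.list(x), fixed)
    if (par$f_S < 0 || par$f_L < 0 || par$f_S + par$f_L > 1) return(-Inf)
    if (par$tau_S >= par$tau_L) return(-Inf)
    f_b <- 1 - par$f_S - par$f_L
    if (taus_free) {
      ps <- component_density(par$tau_S, fixed$T, irf, b)[b$mask]
      pl <- component_density(par$tau_L, fixed$T, irf, b)[b$mask]
    } else {
      ps <- p_s; pl <- p_l
    }
    p <- par$f_S * ps + par$f_L * pl + f_b * u
    sum(counts * log(pmax(p, .PROB_FLOOR)))
  }

  set.seed(as.integer(seed))
  lo <- vapply(bounds, `[`, 0, 1)[free]
  hi <- vapply(bounds, `[`, 0, 2)[free]
  x <- if (is.null(init)) {
    start <- (lo + hi) / 2
    # keep the default start inside the fraction simplex, accounting for
    # any fixed fraction
    frac_free <- intersect(c("f_S", "f_L"), free)
    if (length(frac_free)) {
      frac_fixed <- sum(unlist(fixed[intersect(c("f_S", "f_L"),
                                               names(fixed))]))
      budget <- max(1 - frac_fixed, 1e-6)
      start[frac_free] <- pmin(start[frac_free],
                               0.9 * budget / length(frac_free))
    }
    start
  } else init[free]
  names(x) <- free
  lp <- log_post(x)
  if (!is.finite(lp))
    stop("invalid starting point: zero posterior density", call. = FALSE)

  scales <- 0.1 * (hi - lo)
  n_total <- ceiling(n_samples / (1 - burn_frac))
  n_burn <- n_total - n_samples
  samples <- matrix(NA_real_, n_samples, length(free),
                    dimnames = list(NULL, free))
  acc_total <- 0L
  acc_window <- 0L
  for (i in seq_len(n_total)) {
    prop <- x + stats::rnorm(length(free)) * scales
    prop <- reflect_into(prop, lo, hi)
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      x <- prop; lp <- lp_prop
      acc_total <- acc_total + 1L
      acc_window <- acc_window + 1L
    }
    if (i <= n_burn && i %% 100L == 0L) {
      rate <- acc_window / 100
      if (rate < 0.2) scales <- scales * 0.7
      else if (rate > 0.5) scales <- scales * 1.4
      acc_window <- 0L
    }
    if (i > n_burn) samples[i - n_burn, ] <- x
  }
  if (acc_total == 0L)
    stop(sprintf(
      "MCMC diagnostics: zero acceptance over %d iterations (scales: %s)",
      n_total, paste(signif(scales, 3), collapse = ", ")), call. = FALSE)
  structure(list(samples = samples, acceptance = acc_total / n_total,
                 scales = scales, seed = seed, free = free, fixed = fixed),
            class = "flim_mcmc")
}

# reflect a proposal into [lo, hi] coordinate-wise
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + pmin(y, 2 * w - y)
}

#' @export
print.flim_mcmc <- function(x, ...) {
  cat(sprintf("MCMC posterior: %d samples of (%s); acceptance %.1f%%\n",
              nrow(x$samples), paste(x$free, collapse = ", "),
              100 * x$acceptance))
  invisible(x)
}

#' Monte Carlo standard error by batch means
#'
#' @param x numeric vector of (possibly autocorrelated) MCMC draws.
#' @param n_batches number of batches.
#' @return estimated standard error of the sample mean.
#' @export
mcmc_se <- function(x, n_batches = 20) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(k) mean(x[((k - 1) * bs + 1):(k * bs)]), 0)
  stats::sd(means) / sqrt(n_batches)
}
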