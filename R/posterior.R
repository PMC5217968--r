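#' Parameter grid for posterior evaluation
#'
#' Defines the lattice on which the posterior is evaluated.  Any argument
#' given as a vector of length > 1 becomes a free axis; scalars are held
#' fixed.  Fraction lattices must lie in `[0, 1]`; joint points with
#' `f_S + f_L > 1` (negative background) are excluded, as are points with
#' `tau_S >= tau_L` when lifetimes are free.
#'
#' @param f_S,f_L lattices (or fixed values) for the photon fractions.
#'   Defaults: 201 uniformly spaced points on `[0, 1]`, a resolution of
#'   0.005 per axis.
#' @param tau_S,tau_L lifetime lattices or fixed values, ns.
#' @param T excitation period, ns (always fixed).
#' @return An object of class `"flim_grid"` with fields `axes` (named list
#'   of free lattices), `fixed` (named list) and `points` (data frame of
#'   retained joint parameter points).
#' @examples
#' g <- flim_grid(tau_S = 0.48, tau_L = 4.03)
#' nrow(g$points)
#' @export
flim_grid <- function(f_S = seq(0, 1, length.out = 201),
                      f_L = seq(0, 1, length.out = 201),
                      tau_S = 0.48, tau_L = 4.03, T = 12.5) {
  all_args <- list(f_S = f_S, f_L = f_L, tau_S = tau_S, tau_L = tau_L)
  for (nm in names(all_args)) {
    v <- all_args[[nm]]
    if (!is.numeric(v) || length(v) < 1L || anyNA(v))
      stop(sprintf("'%s' must be numeric and non-missing", nm), call. = FALSE)
    if (length(v) > 1L && any(diff(v) <= 0))
      stop(sprintf("lattice for '%s' must be strictly increasing", nm),
           call. = FALSE)
  }
  if (any(f_S < 0 | f_S > 1) || any(f_L < 0 | f_L > 1))
    stop("fraction lattices must lie in [0, 1]", call. = FALSE)
  if (any(tau_S <= 0) || any(tau_L <= 0) || T <= 0)
    stop("lifetimes and period must be positive", call. = FALSE)
  free <- all_args[vapply(all_args, length, 1L) > 1L]
  fixed <- all_args[vapply(all_args, length, 1L) == 1L]
  fixed$T <- T
  pts <- do.call(expand.grid,
                 c(all_args, list(KEEP.OUT.ATTRS = FALSE)))
  keep <- pts$f_S + pts$f_L <= 1 + 1e-12 & pts$tau_S < pts$tau_L
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0L)
    stop("configuration error: grid is empty after simplex exclusion",
         call. = FALSE)
  rownames(pts) <- NULL
  structure(list(axes = free, fixed = fixed, points = pts, T = T),
            class = "flim_grid")
}

#' @export
print.flim_grid <- function(x, ...) {
  cat(sprintf("parameter grid: %d points; free axes: %s; fixed: %s\n",
              nrow(x$points),
              paste(sprintf("%s[%d]", names(x$axes),
                            lengths(x$axes)), collapse = ", "),
              paste(sprintf("%s=%.4g", names(x$fixed),
                            unlist(x$fixed)), collapse = ", ")))
  invisible(x)
}

#' Posterior over a parameter grid
#'
#' Evaluates the log-likelihood at every retained grid point.  With the
#' uniform prior over the constrained parameter space the posterior is
#' proportional to the likelihood, so the log-density is the
#' log-likelihood up to a constant; the normalization is computed in the
#' log domain by max-subtraction.
#'
#' @param hist a [flim_histogram()].
#' @param grid a [flim_grid()].
#' @param irf a [flim_irf()] on the histogram's binning.
#' @return An object of class `"flim_posterior"`: fields `points` (the
#'   grid's parameter points), `log_density` (unnormalized), `log_norm`
#'   (log of the sum of exponentiated densities) and `axes`.
#' @export
grid_posterior <- function(hist, grid, irf) {
  stopifnot(inherits(hist, "flim_histogram"), inherits(grid, "flim_grid"))
  b <- hist$binning
  w <- irf_weights(irf)
  if (length(w) != b$n_bins)
    stop("shape error: histogram and IRF are on different binnings", call. = FALSE)
  pts <- grid$points
  counts <- hist$counts[b$mask]
  u <- uniform_background(b)[b$mask]
  ld <- numeric(nrow(pts))
  # component densities depend only on the lifetimes: group points by
  # (tau_S, tau_L) and vectorize the fraction mixture within each group
  tau_key <- paste(pts$tau_S, pts$tau_L)
  for (key in unique(tau_key)) {
    idx <- which(tau_key == key)
    p_s <- component_density(pts$tau_S[idx[1]], grid$T, irf, b)[b$mask]
    p_l <- component_density(pts$tau_L[idx[1]], grid$T, irf, b)[b$mask]
    ld[idx] <- loglik_fractions(counts, p_s, p_l, u,
                                pts$f_S[idx], pts$f_L[idx])
  }
  structure(list(points = pts, log_density = ld,
                 log_norm = log_sum_exp(ld), axes = names(grid$axes)),
            class = "flim_posterior")
}

# Vectorized multinomial log-likelihood over fraction combinations:
# counts, p_s, p_l, u are masked-bin vectors; f_s, f_l are equal-length
# vectors of mixture weights.  Returns one log-likelihood per combination.
loglik_fractions <- function(counts, p_s, p_l, u, f_s, f_l) {
  f_b <- pmax(0, 1 - f_s - f_l)
  P <- tcrossprod(f_s, p_s) + tcrossprod(f_l, p_l) + tcrossprod(f_b, u)
  as.numeric(log(pmax(P, .PROB_FLOOR)) %*% counts)
}

#' @export
print.flim_posterior <- function(x, ...) {
  cat(sprintf("grid posterior on %d points (axes: %s)\n",
              nrow(x$points), paste(x$axes, collapse = ", ")))
  invisible(x)
}

#' Marginal posterior of one parameter
#'
#' Sums the normalized posterior mass over all other axes.
#'
#' @param post a [grid_posterior()] result.
#' @param parameter name of a grid axis (e.g. `"f_S"`).
#' @return An object of class `"flim_marginal"` with fields `parameter`,
#'   `values` (ascending lattice) and `mass` (summing to 1).
#' @export
marginalize <- function(post, parameter) {
  stopifnot(inherits(post, "flim_posterior"))
  if (!parameter %in% names(post$points))
    stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  mass <- exp(post$log_density - post$log_norm)
  v <- post$points[[parameter]]
  agg <- vapply(split(mass, v), sum, 0)
  values <- as.numeric(names(agg))
  o <- order(values)
  structure(list(parameter = parameter, values = values[o],
                 mass = unname(agg[o]) / sum(agg)),
            class = "flim_marginal")
}

#' @export
print.flim_marginal <- function(x, ...) {
  cat(sprintf("marginal of %s on %d lattice values; mean %.4g, mode %.4g\n",
              x$parameter, length(x$values),
              post_estimate(x, "mean"), post_estimate(x, "mode")))
  invisible(x)
}

#' Point estimate from a marginal posterior
#'
#' @param marg a [marginalize()] result.
#' @param method `"mean"` (mass-weighted average of the lattice) or
#'   `"mode"` (lattice value of maximal mass; ties broken toward the
#'   smallest value).
#' @return a single number.
#' @export
post_estimate <- function(marg, method = c("mean", "mode")) {
  stopifnot(inherits(marg, "flim_marginal"))
  method <- match.arg(method)
  if (method == "mean") sum(marg$values * marg$mass)
  else marg$values[which.max(marg$mass)]  # values ascending: first max = smallest
}

#' Standard deviation of a marginal posterior
#' @param marg a [marginalize()] result.
#' @return a single non-negative number.
#' @export
marginal_sd <- function(marg) {
  m <- sum(marg$values * marg$mass)
  sqrt(max(0, sum(marg$mass * (marg$values - m)^2)))
}

#' Equal-tail credible interval from a marginal posterior
#'
#' Discrete quantiles of the lattice CDF: the smallest lattice values at
#' which the CDF reaches `alpha/2` and `1 - alpha/2`.
#'
#' @param marg a [marginalize()] result.
#' @param level coverage level, default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(marg, level = 0.95) {
  a <- (1 - level) / 2
  cdf <- cumsum(marg$mass)
  c(lower = marg$values[which(cdf >= a)[1]],
    upper = marg$values[which(cdf >= 1 - a)[1]])
}
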