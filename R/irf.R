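#' Instrument response function on a bin grid
#'
#' Wraps a measured (or synthetic) instrument response as a discrete
#' probability distribution on the acquisition's time bins.  Weights are
#' validated to be non-negative and are normalized to sum to 1.
#'
#' @param weights numeric vector of per-bin IRF intensity (e.g. counts from
#'   a second-harmonic-generation measurement); normalized on construction.
#' @param binning the [flim_binning()] the weights live on.
#' @return An object of class `"flim_irf"`.
#' @export
flim_irf <- function(weights, binning) {
  stopifnot(inherits(binning, "flim_binning"))
  if (!is.numeric(weights) || anyNA(weights))
    stop("IRF weights must be numeric and non-missing", call. = FALSE)
  check_binning_vector(weights, binning, "IRF weights")
  if (any(weights < 0))
    stop("IRF weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("IRF is all zero", call. = FALSE)
  structure(list(weights = weights / s, binning = binning),
            class = "flim_irf")
}

#' @export
print.flim_irf <- function(x, ...) {
  pk <- which.max(x$weights)
  cat(sprintf("IRF on %d bins; peak at bin %d (t = %.4g ns)\n",
              length(x$weights), pk, bin_times(x$binning)[pk]))
  invisible(x)
}

# Accept either a flim_irf or a bare weight vector.
irf_weights <- function(irf) {
  if (inherits(irf, "flim_irf")) irf$weights else as.numeric(irf)
}

#' Synthetic Gaussian IRF
#'
#' A Gaussian timing response integrated over the bins — the usual
#' idealization of a TCSPC system response for simulation work.
#'
#' @param binning a [flim_binning()].
#' @param center peak time in ns (absolute, same origin as the binning).
#' @param sigma width in ns.
#' @return a [flim_irf()].
#' @export
gaussian_irf <- function(binning, center = 0.5, sigma = 0.1) {
  e <- bin_edges(binning)
  w <- stats::pnorm(e$right, center, sigma) - stats::pnorm(e$left, center, sigma)
  flim_irf(w, binning)
}

#' Delta IRF
#'
#' All response weight in a single bin; the identity element of the IRF
#' convolution.  Useful for tests and for data already deconvolved.
#'
#' @param binning a [flim_binning()].
#' @param bin 1-based index of the bin carrying the weight.
#' @return a [flim_irf()].
#' @export
delta_irf <- function(binning, bin = 1L) {
  w <- numeric(binning$n_bins)
  w[as.integer(bin)] <- 1
  flim_irf(w, binning)
}
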