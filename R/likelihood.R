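# floor applied to bin probabilities before log, to keep the log-likelihood
# finite when extreme lifetimes drive bins to underflow
.PROB_FLOOR <- 1e-300

#' Multinomial log-likelihood of a histogram under the mixture model
#'
#' Computes `sum_i P_i * log p_i(theta)` over the masked-in bins, the
#' log of the multinomial likelihood up to the theta-independent
#' combinatorial constant (which cancels in any posterior).  Bin
#' probabilities are floored at `1e-300` before the log.
#'
#' @param hist a [flim_histogram()].
#' @param theta a [decay_params()].
#' @param irf a [flim_irf()] on the same binning as `hist`.
#' @return a single finite number.
#' @export
log_likelihood <- function(hist, theta, irf) {
  stopifnot(inherits(hist, "flim_histogram"), inherits(theta, "decay_params"))
  b <- hist$binning
  w <- irf_weights(irf)
  if (length(w) != b$n_bins)
    stop("shape error: histogram and IRF are on different binnings", call. = FALSE)
  p <- mixture_bin_probabilities(theta, irf, b)
  m <- b$mask
  sum(hist$counts[m] * log(pmax(p[m], .PROB_FLOOR)))
}

# log(sum(exp(x))) with max subtraction
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
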