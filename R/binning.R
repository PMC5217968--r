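#' TCSPC time binning
#'
#' Describes the discrete time axis of a TCSPC acquisition: `n_bins`
#' contiguous half-open bins `[(i-1)*dt + t0, i*dt + t0)` of width `dt`
#' nanoseconds, together with a logical mask marking which bins fall inside
#' the recorded TAC window.  Bins outside the mask carry no probability and
#' their counts are ignored by the likelihood.
#'
#' @param n_bins number of bins (positive integer).
#' @param dt bin width in nanoseconds.
#' @param t0 time of the left edge of bin 1 relative to the excitation
#'   pulse, in nanoseconds.  Defaults to 0.
#' @param mask logical vector of length `n_bins`; `TRUE` marks a recorded
#'   bin.  Defaults to all bins recorded.
#' @return An object of class `"flim_binning"`.
#' @examples
#' b <- flim_binning(256, dt = 10 / 256)
#' bin_times(b)[1:3]
#' @export
flim_binning <- function(n_bins, dt, t0 = 0, mask = NULL) {
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 1L)
    stop("'n_bins' must be a positive integer", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a positive bin width in ns", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || t0 < 0)
    stop("'t0' must be a non-negative time in ns", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, n_bins)
  mask <- as.logical(mask)
  if (length(mask) != n_bins || anyNA(mask))
    stop("'mask' must be a logical vector of length n_bins", call. = FALSE)
  if (!any(mask))
    stop("degenerate binning: at least one bin must be inside the recorded window",
         call. = FALSE)
  structure(list(n_bins = n_bins, dt = dt, t0 = t0, mask = mask),
            class = "flim_binning")
}

#' Left and right bin-edge times
#'
#' @param binning a [flim_binning()] object.
#' @return `bin_times()` returns the left edges; `bin_edges()` returns a
#'   list with components `left` and `right` (ns).
#' @export
bin_times <- function(binning) {
  stopifnot(inherits(binning, "flim_binning"))
  binning$t0 + (seq_len(binning$n_bins) - 1) * binning$dt
}

#' @rdname bin_times
#' @export
bin_edges <- function(binning) {
  left <- bin_times(binning)
  list(left = left, right = left + binning$dt)
}

#' @export
print.flim_binning <- function(x, ...) {
  cat(sprintf("TCSPC binning: %d bins of %.6g ns (window %.6g-%.6g ns), %d recorded\n",
              x$n_bins, x$dt, x$t0, x$t0 + x$n_bins * x$dt, sum(x$mask)))
  invisible(x)
}

#' Build a bin mask from TAC window limits
#'
#' Convenience for configurations that give the recorded window as a pair
#' of bin indices rather than a logical vector.
#'
#' @param n_bins total number of bins.
#' @param low,high first and last recorded bin (1-based, inclusive).
#' @return logical vector of length `n_bins`.
#' @export
window_mask <- function(n_bins, low = 1L, high = n_bins) {
  n_bins <- as.integer(n_bins); low <- as.integer(low); high <- as.integer(high)
  if (low < 1L || high > n_bins || low > high)
    stop("invalid window limits", call. = FALSE)
  seq_len(n_bins) >= low & seq_len(n_bins) <= high
}

# shared validation: probabilities on a binning grid
check_binning_vector <- function(x, binning, what = "vector") {
  if (length(x) != binning$n_bins)
    stop(sprintf("%s has length %d but the binning has %d bins",
                 what, length(x), binning$n_bins), call. = FALSE)
  invisible(TRUE)
}
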