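#' Binned photon arrival-time histogram
#'
#' The basic data object: non-negative integer photon counts per time bin.
#' Counts in masked-out bins are retained for bookkeeping but never enter
#' the likelihood; `n_photons` always refers to the masked-in total.
#'
#' @param counts non-negative integer vector, one entry per bin.
#' @param binning a [flim_binning()].
#' @return An object of class `"flim_histogram"` with fields `counts`,
#'   `binning`, `n_photons`.
#' @export
flim_histogram <- function(counts, binning) {
  stopifnot(inherits(binning, "flim_binning"))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and non-missing", call. = FALSE)
  check_binning_vector(counts, binning, "counts")
  if (any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers", call. = FALSE)
  counts <- round(counts)
  structure(list(counts = counts, binning = binning,
                 n_photons = sum(counts[binning$mask])),
            class = "flim_histogram")
}

#' @export
print.flim_histogram <- function(x, ...) {
  cat(sprintf("FLIM histogram: %s photons in %d recorded bins (of %d)\n",
              format(x$n_photons, big.mark = ","), sum(x$binning$mask),
              x$binning$n_bins))
  invisible(x)
}

#' Restrict a histogram to a bin mask
#'
#' Drops the counts of newly masked-out bins (combining the given mask with
#' the histogram's existing one), mirroring [apply_bin_mask()] on the model
#' side.
#'
#' @param hist a [flim_histogram()].
#' @param mask logical vector over bins; `TRUE` = keep.
#' @return a [flim_histogram()] on the reduced mask.
#' @export
mask_histogram <- function(hist, mask) {
  stopifnot(inherits(hist, "flim_histogram"))
  b <- hist$binning
  mask <- as.logical(mask)
  if (length(mask) != b$n_bins) stop("mask length mismatch", call. = FALSE)
  new_mask <- b$mask & mask
  if (!any(new_mask))
    stop("degenerate binning: mask retains no bins", call. = FALSE)
  counts <- hist$counts
  counts[!new_mask] <- 0
  flim_histogram(counts, flim_binning(b$n_bins, b$dt, b$t0, new_mask))
}
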