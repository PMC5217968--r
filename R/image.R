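#' FLIM image container
#'
#' A 2-D grid of per-pixel photon arrival histograms sharing one time
#' binning, stored as a `ny x nx x n_bins` array.
#'
#' @param counts integer array of dimension `c(ny, nx, n_bins)`.
#' @param binning a [flim_binning()].
#' @return An object of class `"flim_image"`.
#' @export
flim_image <- function(counts, binning) {
  stopifnot(inherits(binning, "flim_binning"))
  d <- dim(counts)
  if (length(d) != 3L || d[3] != binning$n_bins)
    stop("counts must be a ny x nx x n_bins array", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, binning = binning,
                 ny = d[1], nx = d[2]),
            class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  cat(sprintf("FLIM image: %d x %d pixels, %d time bins, %s photons total\n",
              x$ny, x$nx, x$binning$n_bins,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Boxcar-pooled per-pixel fraction fitting
#'
#' For every pixel, pools the histograms of the centered `window x window`
#' neighborhood (truncated at the image borders), fits the mixture model
#' with fixed lifetimes, and reports the long-lifetime amplitude fraction
#' (`1 - a_S`, see [amplitude_fraction()]).  Pixels whose pooled photon
#' count falls below `min_photons` are left `NA`; the map mean and s.d.
#' are computed over the fitted pixels.
#'
#' @param img a [flim_image()].
#' @param window odd boxcar size in pixels (1, 3, 7, 11, ...).
#' @param irf a [flim_irf()] on the image's binning.
#' @param tau_S,tau_L fixed lifetimes, ns.
#' @param period excitation period, ns.
#' @param method `"bayes"` (adaptive grid posterior, posterior-mean
#'   fractions) or `"ls"` (weighted least squares).
#' @param min_photons minimum pooled photons for a pixel to be fitted.
#' @return An object of class `"flim_fraction_map"`: `map` (matrix of
#'   long-lifetime amplitude fractions), `n_photons` (pooled counts),
#'   `mean`, `sd`, `window`, `method`.
#' @export
boxcar_fit_image <- function(img, window = 3, irf, tau_S = 0.48,
                             tau_L = 4.03, period = 12.5,
                             method = c("bayes", "ls"), min_photons = 100) {
  stopifnot(inherits(img, "flim_image"))
  method <- match.arg(method)
  if (window %% 2 != 1 || window < 1 || window > min(img$ny, img$nx))
    stop("'window' must be an odd pixel count no larger than the image",
         call. = FALSE)
  b <- img$binning
  half <- (window - 1) / 2
  engine <- if (method == "bayes")
    fraction_fitter(irf, b, tau_S, tau_L, period)
  map <- matrix(NA_real_, img$ny, img$nx)
  nph <- matrix(0, img$ny, img$nx)
  for (i in seq_len(img$ny)) {
    ys <- max(1, i - half):min(img$ny, i + half)
    for (j in seq_len(img$nx)) {
      xs <- max(1, j - half):min(img$nx, j + half)
      pooled <- apply(img$counts[ys, xs, , drop = FALSE], 3, sum)
      nph[i, j] <- sum(pooled[b$mask])
      if (nph[i, j] < min_photons) next
      if (method == "bayes") {
        f <- engine(pooled)
        f_s <- f$estimates$mean[f$estimates$parameter == "f_S"]
        f_l <- f$estimates$mean[f$estimates$parameter == "f_L"]
        if (f_s + f_l <= 0) next
        th <- decay_params(f_s, min(f_l, 1 - f_s), tau_S, tau_L, period)
        map[i, j] <- 1 - amplitude_fraction(th, b)
      } else {
        ls <- least_squares_fractions(flim_histogram(pooled, b), irf,
                                      tau_S, tau_L, period)
        map[i, j] <- ls$amp_long
      }
    }
  }
  structure(list(map = map, n_photons = nph,
                 mean = mean(map, na.rm = TRUE),
                 sd = stats::sd(as.numeric(map), na.rm = TRUE),
                 window = window, method = method),
            class = "flim_fraction_map")
}

#' @export
print.flim_fraction_map <- function(x, ...) {
  cat(sprintf("%s long-lifetime amplitude-fraction map, %dx%d boxcar: mean %.4f, s.d. %.4f (%d/%d pixels fit)\n",
              x$method, x$window, x$window, x$mean, x$sd,
              sum(!is.na(x$map)), length(x$map)))
  invisible(x)
}
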