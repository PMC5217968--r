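#' Default synthetic acquisition
#'
#' The acquisition geometry used throughout the validation studies: 256
#' bins over a 10 ns recorded window, 12.5 ns excitation period (80 MHz),
#' and a Gaussian IRF of width 0.1 ns centered 0.5 ns into the window.
#'
#' @return list with components `binning`, `irf`, `period`.
#' @export
default_acquisition <- function() {
  b <- flim_binning(256, dt = 10 / 256, t0 = 0)
  list(binning = b, irf = gaussian_irf(b, center = 0.5, sigma = 0.1),
       period = 12.5)
}

#' Simulate a binned TCSPC histogram
#'
#' Fast path of the simulator: draws the bin counts directly from a
#' multinomial over [mixture_bin_probabilities()], which is exact for any
#' analysis that only sees the binned data.
#'
#' @param theta a [decay_params()].
#' @param irf a [flim_irf()].
#' @param binning a [flim_binning()].
#' @param n_photons number of recorded photons (>= 0).
#' @param seed optional integer seed; when given the draw is fully
#'   determined by it, otherwise the current RNG stream is used.
#' @return a [flim_histogram()].
#' @export
simulate_histogram <- function(theta, irf, binning, n_photons, seed = NULL) {
  stopifnot(inherits(theta, "decay_params"), inherits(binning, "flim_binning"))
  if (n_photons < 0) stop("'n_photons' must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- mixture_bin_probabilities(theta, irf, binning)
  counts <- as.integer(stats::rmultinom(1, size = n_photons, prob = p))
  flim_histogram(counts, binning)
}

#' Simulate continuous photon arrival times
#'
#' Per-photon generative path, used to validate the binned model: each
#' photon picks a source by the fractions `(f_S, f_L, f_B)`; decay photons
#' get an exponential emission delay added to an IRF-sampled arrival
#' offset (the IRF, measured at bin resolution, contributes the sampled
#' bin's grid time) and are wrapped modulo the excitation period;
#' background photons are uniform over the recorded window.  Photons
#' falling outside the recorded (masked-in) window are redrawn *within
#' their component* (each component is conditioned on detection inside the
#' window, mirroring the model's per-component window renormalization), so
#' `n_photons` counts recorded photons and the recorded composition is
#' exactly `(f_S, f_L, f_B)` in expectation.  When the period is an
#' integer number of bin widths, binning the returned times reproduces the
#' distribution sampled by [simulate_histogram()] exactly.
#'
#' @inheritParams simulate_histogram
#' @return numeric vector of `n_photons` arrival times (ns) inside the
#'   recorded window.  Bin it with [bin_photons()].
#' @export
simulate_photons <- function(theta, irf, binning, n_photons, seed = NULL) {
  stopifnot(inherits(theta, "decay_params"), inherits(binning, "flim_binning"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- irf_weights(irf)
  b <- binning
  masked_bins <- which(b$mask)
  comp <- sample.int(3L, n_photons, replace = TRUE,
                     prob = c(theta$f_S, theta$f_L, theta$f_B))
  n_comp <- tabulate(comp, nbins = 3L)

  # decay components: IRF grid time + exponential delay, wrapped mod T,
  # rejected (within the component) until inside the recorded window
  draw_decay <- function(n, tau) {
    out <- numeric(0)
    tries <- 0L
    while (length(out) < n) {
      need <- n - length(out)
      m <- need + ceiling(0.25 * need) + 16L
      irf_bin <- sample.int(b$n_bins, m, replace = TRUE, prob = w)
      rel <- ((irf_bin - 1) * b$dt + stats::rexp(m, rate = 1 / tau)) %% theta$T
      idx <- floor(rel / b$dt) + 1
      ok <- idx >= 1 & idx <= b$n_bins
      ok[ok] <- b$mask[idx[ok]]
      out <- c(out, b$t0 + rel[ok])
      tries <- tries + 1L
      if (tries > 1000L && length(out) == 0L)
        stop("degenerate model: recorded window has vanishing probability",
             call. = FALSE)
    }
    out[seq_len(n)]
  }
  t <- numeric(n_photons)
  if (n_comp[1] > 0) t[comp == 1L] <- draw_decay(n_comp[1], theta$tau_S)
  if (n_comp[2] > 0) t[comp == 2L] <- draw_decay(n_comp[2], theta$tau_L)
  if (n_comp[3] > 0) {
    bg_bin <- masked_bins[sample.int(length(masked_bins), n_comp[3],
                                     replace = TRUE)]
    t[comp == 3L] <- b$t0 + (bg_bin - 1 + stats::runif(n_comp[3])) * b$dt
  }
  t
}

#' Bin continuous arrival times on a binning grid
#'
#' @param times numeric vector of arrival times (ns).
#' @param binning a [flim_binning()].
#' @return a [flim_histogram()]; times outside the grid are dropped.
#' @export
bin_photons <- function(times, binning) {
  idx <- floor((times - binning$t0) / binning$dt) + 1
  idx <- idx[idx >= 1 & idx <= binning$n_bins]
  flim_histogram(tabulate(idx, nbins = binning$n_bins), binning)
}

#' Synthetic master curve
#'
#' A very-high-count arrival-time histogram standing in for the dye
#' "master" measurements from which test histograms are subsampled.  The
#' counts are the expected counts of the mixture model at `n_effective`
#' photons (rounded), so the master is a deterministic, essentially
#' noise-free rendering of the generating distribution.
#'
#' @param theta the generating [decay_params()].
#' @param irf a [flim_irf()].
#' @param binning a [flim_binning()].
#' @param n_effective effective photon count of the master (default 1e9).
#' @param label free-text source label (`"mixture"`, `"short-only"`, ...).
#' @return An object of class `"flim_master"` with fields `counts`,
#'   `binning`, `theta`, `irf`, `label`, `total`.
#' @export
master_curve <- function(theta, irf, binning, n_effective = 1e9,
                         label = "mixture") {
  stopifnot(inherits(theta, "decay_params"))
  p <- mixture_bin_probabilities(theta, irf, binning)
  counts <- round(n_effective * p)
  if (sum(counts) <= 0) stop("empty master curve", call. = FALSE)
  structure(list(counts = counts, binning = binning, theta = theta,
                 irf = irf, label = label, total = sum(counts)),
            class = "flim_master")
}

#' @export
print.flim_master <- function(x, ...) {
  cat(sprintf("master curve (%s): %.3g photons over %d bins; f_S = %.3g\n",
              x$label, x$total, x$binning$n_bins, x$theta$f_S))
  invisible(x)
}

#' Subsample a master curve
#'
#' Draws `n_photons` photons i.i.d. across bins with probabilities
#' proportional to the master counts (multinomial, i.e. sampling with
#' replacement) — the resampling step of the low-photon study.
#'
#' @param master a [master_curve()].
#' @param n_photons number of photons to draw.
#' @param seed optional integer seed.
#' @return a [flim_histogram()].
#' @export
subsample_master <- function(master, n_photons, seed = NULL) {
  stopifnot(inherits(master, "flim_master"))
  if (master$total < 1) stop("empty master curve", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- as.integer(stats::rmultinom(1, size = n_photons,
                                        prob = master$counts))
  flim_histogram(counts, master$binning)
}

#' Mix two master curves at a prescribed short fraction
#'
#' Draws `round(f_S_prescribed * n_total)` photons (round half away from
#' zero) from the short-lifetime master and the remainder from the
#' long-lifetime master, and sums the two histograms — the construction of
#' the low-fraction study.
#'
#' @param short,long [master_curve()] objects on the same binning.
#' @param f_S_prescribed prescribed fraction drawn from the short master,
#'   in `[0, 1]`.
#' @param n_total total number of photons.
#' @param seed optional integer seed.
#' @return a [flim_histogram()] with exactly `n_total` photons.
#' @export
mix_masters <- function(short, long, f_S_prescribed, n_total, seed = NULL) {
  stopifnot(inherits(short, "flim_master"), inherits(long, "flim_master"))
  if (!is.numeric(f_S_prescribed) || f_S_prescribed < 0 || f_S_prescribed > 1)
    stop("invalid parameter: prescribed fraction must be in [0, 1]",
         call. = FALSE)
  if (short$binning$n_bins != long$binning$n_bins)
    stop("masters are on different binnings", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_short <- floor(f_S_prescribed * n_total + 0.5)  # round half away from zero
  hs <- subsample_master(short, n_short)
  hl <- subsample_master(long, n_total - n_short)
  flim_histogram(hs$counts + hl$counts, short$binning)
}

#' Simulate a uniform synthetic FLIM image
#'
#' Every pixel gets an independent multinomial histogram from the same
#' generating parameters — the null field used to measure how boxcar
#' pooling trades spatial resolution for per-fit precision.
#'
#' @param theta a [decay_params()].
#' @param irf a [flim_irf()].
#' @param binning a [flim_binning()].
#' @param ny,nx image size in pixels.
#' @param n_photons_per_pixel photons per pixel.
#' @param seed optional integer seed.
#' @return a [flim_image()].
#' @export
simulate_flim_image <- function(theta, irf, binning, ny, nx,
                                n_photons_per_pixel, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- mixture_bin_probabilities(theta, irf, binning)
  counts <- stats::rmultinom(ny * nx, size = n_photons_per_pixel, prob = p)
  arr <- array(0L, dim = c(ny, nx, binning$n_bins))
  for (k in seq_len(ny * nx)) {
    i <- (k - 1) %% ny + 1
    j <- (k - 1) %/% ny + 1
    arr[i, j, ] <- counts[, k]
  }
  flim_image(arr, binning)
}
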