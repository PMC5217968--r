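#' Biexponential decay model parameters
#'
#' The parameter vector of the mixture model for photon arrival times: a
#' short-lifetime component (fraction `f_S`, lifetime `tau_S`), a
#' long-lifetime component (fraction `f_L`, lifetime `tau_L`) and a uniform
#' background occupying the remaining fraction `f_B = 1 - f_S - f_L`.  `T`
#' is the excitation pulse period in nanoseconds (12.5 ns for an 80 MHz
#' laser).
#'
#' The background fraction is always derived from the two photon fractions,
#' so the simplex constraint holds by construction; the call is rejected if
#' `f_S + f_L > 1`, if any fraction falls outside `[0, 1]`, or if the
#' lifetimes are not ordered `tau_S < tau_L`.
#'
#' @param f_S,f_L photon fractions of the short- and long-lifetime
#'   components, each in `[0, 1]` with `f_S + f_L <= 1`.
#' @param tau_S,tau_L component lifetimes in ns, `0 < tau_S < tau_L`.
#' @param T excitation period in ns.
#' @return An object of class `"decay_params"` with fields `f_S`, `f_L`,
#'   `f_B`, `tau_S`, `tau_L`, `T`.
#' @examples
#' decay_params(0.3, 0.6, tau_S = 0.48, tau_L = 4.03, T = 12.5)
#' @export
decay_params <- function(f_S, f_L, tau_S, tau_L, T = 12.5) {
  vals <- c(f_S = f_S, f_L = f_L, tau_S = tau_S, tau_L = tau_L, T = T)
  if (!is.numeric(vals) || anyNA(vals))
    stop("all decay parameters must be finite numbers", call. = FALSE)
  if (f_S < 0 || f_S > 1 || f_L < 0 || f_L > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (f_S + f_L > 1 + 1e-12)
    stop("f_S + f_L exceeds 1; the background fraction would be negative",
         call. = FALSE)
  if (tau_S <= 0 || tau_L <= 0 || T <= 0)
    stop("lifetimes and period must be positive", call. = FALSE)
  if (tau_S >= tau_L)
    stop("lifetime ordering violated: require tau_S < tau_L", call. = FALSE)
  f_B <- max(0, 1 - f_S - f_L)
  structure(list(f_S = f_S, f_L = f_L, f_B = f_B,
                 tau_S = tau_S, tau_L = tau_L, T = T),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("decay parameters: f_S = %.4g, f_L = %.4g, f_B = %.4g; tau_S = %.4g ns, tau_L = %.4g ns; T = %.4g ns\n",
              x$f_S, x$f_L, x$f_B, x$tau_S, x$tau_L, x$T))
  invisible(x)
}

#' Per-bin probabilities of a periodically excited exponential decay
#'
#' Under pulsed excitation with period `T`, photons excited by earlier
#' pulses pile onto the current period, turning the single-pulse density
#' `exp(-t/tau)` into a geometric sum whose closed form is
#' `exp(-t/tau) / (1 - exp(-T/tau))` on one period.  The constant prefactor
#' is absorbed by the final normalization, so the probability of a bin
#' `[t_l, t_r)` is proportional to `exp(-t_l/tau) - exp(-t_r/tau)` (the
#' exact integral of the density over the bin), renormalized over the
#' recorded (masked-in) bins.
#'
#' @param tau lifetime in ns (> 0).
#' @param T excitation period in ns (> 0).
#' @param binning a [flim_binning()].
#' @return numeric vector of length `n_bins`; masked-out bins are 0 and the
#'   masked-in bins sum to 1.
#' @export
periodic_decay_density <- function(tau, T, binning) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("invalid parameter: 'tau' must be a positive lifetime", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0)
    stop("invalid parameter: 'T' must be a positive period", call. = FALSE)
  stopifnot(inherits(binning, "flim_binning"))
  e <- bin_edges(binning)
  mass <- exp(-e$left / tau) - exp(-e$right / tau)
  mass[!binning$mask] <- 0
  s <- sum(mass)
  if (s <= 0) stop("degenerate binning: no probability mass in recorded bins",
                   call. = FALSE)
  mass / s
}

# Unnormalized periodic decay bin masses on an arbitrary edge grid.
decay_bin_mass <- function(tau, left, right) {
  exp(-left / tau) - exp(-right / tau)
}

#' Circular convolution of bin probabilities with an IRF
#'
#' Convolves a per-bin decay distribution with the instrument response,
#' both given at bin resolution on the same grid.  The convolution is
#' circular: mass shifted past the last bin wraps to the first, reflecting
#' the periodicity of the steady-state arrival distribution.  The result is
#' renormalized over the masked-in bins.
#'
#' When the recorded grid spans exactly one excitation period this is the
#' mod-`T` convolution of the mixture model; for shorter windows the wrap
#' occurs at the window edge (the mixture model itself convolves on an
#' extended full-period grid, see [component_density()]).
#'
#' @param p numeric vector of per-bin probabilities on the full grid.
#' @param irf a [flim_irf()] on the same binning (or a bare weight vector
#'   of the same length).
#' @param binning a [flim_binning()].
#' @return numeric vector of per-bin probabilities (masked-in bins sum
#'   to 1).
#' @export
convolve_irf <- function(p, irf, binning) {
  stopifnot(inherits(binning, "flim_binning"))
  w <- irf_weights(irf)
  check_binning_vector(p, binning, "'p'")
  if (length(w) != length(p))
    stop("shape error: decay and IRF are on different grids", call. = FALSE)
  out <- circular_convolve(p, w)
  out[!binning$mask] <- 0
  s <- sum(out)
  if (s <= 0) stop("degenerate binning: convolved mass vanishes on recorded bins",
                   call. = FALSE)
  out / s
}

# FFT-based circular convolution c_m = sum_j a_j b_{m-j+1 (mod n)}.
circular_convolve <- function(a, b) {
  n <- length(a)
  out <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / n
  pmax(out, 0)  # clip FFT roundoff
}

#' Single-component arrival distribution: periodic decay convolved with IRF
#'
#' Computes the per-bin arrival probability of one exponential component as
#' used inside the mixture model: the periodic decay density is evaluated
#' on a grid extended to one full excitation period (when `T` is an integer
#' number of bin widths), circularly convolved with the zero-padded IRF
#' modulo `T`, truncated to the recorded window, and renormalized over the
#' masked-in bins.  If `T` is not commensurate with the bin width the
#' convolution falls back to wrapping at the recorded-grid edge.
#'
#' @inheritParams periodic_decay_density
#' @param irf a [flim_irf()] on `binning`.
#' @return numeric vector of length `n_bins`; masked-in bins sum to 1.
#' @export
component_density <- function(tau, T, irf, binning) {
  stopifnot(inherits(binning, "flim_binning"))
  if (tau <= 0 || T <= 0)
    stop("invalid parameter: lifetimes and period must be positive", call. = FALSE)
  w <- irf_weights(irf)
  check_binning_vector(w, binning, "IRF")
  n <- binning$n_bins
  n_ext <- round(T / binning$dt)
  if (n_ext >= n && abs(n_ext * binning$dt - T) < 1e-9 * T) {
    left <- binning$t0 + (seq_len(n_ext) - 1) * binning$dt
    mass <- decay_bin_mass(tau, left, left + binning$dt)
    out <- circular_convolve(mass, c(w, rep(0, n_ext - n)))[seq_len(n)]
  } else {
    e <- bin_edges(binning)
    out <- circular_convolve(decay_bin_mass(tau, e$left, e$right), w)
  }
  out[!binning$mask] <- 0
  s <- sum(out)
  if (s <= 0) stop("degenerate binning: component mass vanishes on recorded bins",
                   call. = FALSE)
  out / s
}

#' Mixture model per-bin arrival probabilities
#'
#' The per-bin probability under the full model: short and long exponential
#' components (each a periodic decay convolved with the IRF and normalized
#' over the recorded window) weighted by their photon fractions, plus a
#' uniform background over the recorded bins.
#'
#' @param theta a [decay_params()] object.
#' @param irf a [flim_irf()] on `binning`.
#' @param binning a [flim_binning()].
#' @return numeric vector of length `n_bins` summing to 1 over masked-in
#'   bins.
#' @examples
#' b <- flim_binning(256, 10 / 256)
#' irf <- gaussian_irf(b, center = 0.5, sigma = 0.1)
#' th <- decay_params(0.3, 0.6, 0.48, 4.03)
#' p <- mixture_bin_probabilities(th, irf, b)
#' sum(p)
#' @export
mixture_bin_probabilities <- function(theta, irf, binning) {
  stopifnot(inherits(theta, "decay_params"), inherits(binning, "flim_binning"))
  p_s <- component_density(theta$tau_S, theta$T, irf, binning)
  p_l <- component_density(theta$tau_L, theta$T, irf, binning)
  u <- uniform_background(binning)
  theta$f_S * p_s + theta$f_L * p_l + theta$f_B * u
}

# uniform distribution over masked-in bins
uniform_background <- function(binning) {
  u <- numeric(binning$n_bins)
  u[binning$mask] <- 1 / sum(binning$mask)
  u
}

#' Remove time bins and renormalize
#'
#' Drops the probability in masked-out bins and renormalizes the retained
#' bins so they sum to 1; applied to a histogram this corresponds to
#' conditioning the multinomial on arrival within the retained bins.
#'
#' @param p numeric vector of per-bin probabilities.
#' @param mask logical vector; `TRUE` marks retained bins.
#' @return numeric vector with masked-out bins 0 and retained bins summing
#'   to 1.
#' @export
apply_bin_mask <- function(p, mask) {
  mask <- as.logical(mask)
  if (length(mask) != length(p))
    stop("mask length does not match the number of bins", call. = FALSE)
  if (!any(mask))
    stop("degenerate binning: mask retains no bins", call. = FALSE)
  out <- ifelse(mask, p, 0)
  s <- sum(out)
  if (s <= 0)
    stop("degenerate binning: retained bins carry no probability", call. = FALSE)
  out / s
}
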