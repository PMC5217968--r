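#' Power-law fit on log-log axes
#'
#' Fits `y = a * x^b` by ordinary least squares of `log10(y)` on
#' `log10(x)`, optionally excluding the `exclude_lowest` smallest-`x`
#' points (the scaling studies exclude the lowest photon counts, where
#' boundary truncation of the estimates flattens the curve).
#'
#' @param x,y positive numeric vectors (>= 3 points after exclusion).
#' @param exclude_lowest number of lowest-`x` points to drop.
#' @return An object of class `"power_law_fit"`: `a`, `b`, `ci_a`, `ci_b`
#'   (95% confidence half-widths), `n_points`, and the underlying `lm`
#'   fit.
#' @examples
#' fit_power_law(c(10, 100, 1000), 2 * c(10, 100, 1000)^-0.5)
#' @export
fit_power_law <- function(x, y, exclude_lowest = 0) {
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit requires strictly positive x and y", call. = FALSE)
  if (exclude_lowest > 0) {
    keep <- rank(x, ties.method = "first") > exclude_lowest
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3)
    stop("power-law fit needs at least 3 points", call. = FALSE)
  fit <- stats::lm(ly ~ lx, data = data.frame(lx = log10(x), ly = log10(y)))
  # confint warns on zero-residual (exact) fits; the intervals are still valid
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  a <- 10^stats::coef(fit)[[1]]
  structure(list(a = a, b = stats::coef(fit)[[2]],
                 ci_a = diff(10^ci[1, ]) / 2, ci_b = diff(ci[2, ]) / 2,
                 n_points = length(x), lm = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law a*x^b: a = %.4g +/- %.2g, b = %.4g +/- %.2g (95%% CI, %d points)\n",
              x$a, x$ci_a, x$b, x$ci_b, x$n_points))
  invisible(x)
}

#' Evaluate a fitted power law
#' @param fit a [fit_power_law()] result (or a list with `a` and `b`).
#' @param x evaluation points.
#' @return `a * x^b`.
#' @export
predict_power_law <- function(fit, x) fit$a * x^fit$b

# OLS line with 95% half-widths, used by the linearity analyses
ols_line <- function(x, y) {
  fit <- stats::lm(y ~ x)
  ci <- suppressWarnings(stats::confint(fit))
  list(offset = stats::coef(fit)[[1]], slope = stats::coef(fit)[[2]],
       ci_offset = diff(ci[1, ]) / 2, ci_slope = diff(ci[2, ]) / 2)
}

#' Low-photon resampling study
#'
#' Replicates the subsampling protocol of the low-photon validation: from
#' a mixture master curve, draw `n_reps` independent subsamples at each
#' photon count, fit each subsample with the lifetimes held fixed, and
#' collect the posterior-mean and posterior-mode estimates of `f_S`.
#' Per-condition summaries report the sample mean, s.d., s.e.m. and bias
#' against the master's generating `f_S`.
#'
#' @param master a [master_curve()] (its `theta` and `irf` define the
#'   generating truth and the fitting model).
#' @param photon_counts vector of total photon counts per condition.
#' @param n_reps replicates per condition (>= 2).
#' @param seed integer seed; the whole study is reproducible from it.
#' @param n_coarse coarse lattice size passed to the grid fitter.
#' @return An object of class `"flim_study"` (kind `"low_photon"`):
#'   `conditions` (per-count summaries), `replicates` (every estimate),
#'   `true_f_S`, `seed`.
#' @export
low_photon_study <- function(master, photon_counts, n_reps = 300, seed = 1,
                             n_coarse = 201) {
  stopifnot(inherits(master, "flim_master"))
  if (any(photon_counts < 1)) stop("photon counts must be >= 1", call. = FALSE)
  if (n_reps < 2) stop("need at least 2 replicates", call. = FALSE)
  set.seed(as.integer(seed))
  th <- master$theta
  engine <- fraction_fitter(master$irf, master$binning, th$tau_S, th$tau_L,
                            th$T, n_coarse = n_coarse)
  photon_counts <- sort(photon_counts)
  reps <- vector("list", length(photon_counts))
  for (ci in seq_along(photon_counts)) {
    n <- photon_counts[ci]
    est <- matrix(NA_real_, n_reps, 2)
    for (r in seq_len(n_reps)) {
      h <- subsample_master(master, n)
      f <- tryCatch(engine(h), error = function(e) {
        warning(sprintf("fit failed at n=%g rep %d: %s", n, r,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(f)) next
      est[r, ] <- c(f$estimates$mean[f$estimates$parameter == "f_S"],
                    f$estimates$mode[f$estimates$parameter == "f_S"])
    }
    reps[[ci]] <- data.frame(n_photons = n, rep = seq_len(n_reps),
                             est_mean = est[, 1], est_mode = est[, 2])
  }
  replicates <- do.call(rbind, reps)
  conditions <- summarize_conditions(replicates, "n_photons", th$f_S)
  structure(list(kind = "low_photon", conditions = conditions,
                 replicates = replicates, true_f_S = th$f_S,
                 n_reps = n_reps, seed = seed),
            class = "flim_study")
}

# per-condition mean/sd/sem/bias for both estimators
summarize_conditions <- function(replicates, axis, true_value) {
  sp <- split(replicates, replicates[[axis]])
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      axis = d[[axis]][1],
      mean_est_mean = mean(d$est_mean, na.rm = TRUE),
      sd_est_mean = stats::sd(d$est_mean, na.rm = TRUE),
      sem_est_mean = stats::sd(d$est_mean, na.rm = TRUE) /
        sqrt(sum(!is.na(d$est_mean))),
      mean_est_mode = mean(d$est_mode, na.rm = TRUE),
      sd_est_mode = stats::sd(d$est_mode, na.rm = TRUE),
      sem_est_mode = stats::sd(d$est_mode, na.rm = TRUE) /
        sqrt(sum(!is.na(d$est_mode))),
      n_ok = sum(!is.na(d$est_mean)))
  }))
  names(out)[1] <- axis
  if (!is.null(true_value) && length(true_value) == 1) {
    out$bias_mean <- out$mean_est_mean - true_value
    out$bias_mode <- out$mean_est_mode - true_value
  }
  out <- out[order(out[[axis]]), ]
  rownames(out) <- NULL
  out
}

#' @export
print.flim_study <- function(x, ...) {
  cat(sprintf("%s study: %d conditions x %d replicates\n",
              x$kind, nrow(x$conditions), x$n_reps))
  print(x$conditions, digits = 4, row.names = FALSE)
  if (!is.null(x$linear_fit_mean))
    cat(sprintf("linearity (mean estimator): slope %.4f +/- %.4f, offset %.3g +/- %.3g\n",
                x$linear_fit_mean$slope, x$linear_fit_mean$ci_slope,
                x$linear_fit_mean$offset, x$linear_fit_mean$ci_offset))
  invisible(x)
}

#' Low-fraction mixing study
#'
#' Replicates the master-mixing protocol of the low-fraction validation:
#' for each prescribed short fraction, build `n_reps` mixed histograms of
#' `n_total` photons from separate short- and long-lifetime masters
#' ([mix_masters()]), fit each with lifetimes fixed, and regress the
#' per-condition mean estimated fraction on the prescribed fraction.
#'
#' @param short_master,long_master [master_curve()] objects (the short
#'   master's `irf`/lifetimes drive the fitter).
#' @param fractions prescribed short fractions, strictly inside `(0, 1)`.
#' @param n_total total photons per mixed histogram.
#' @param n_reps replicates per fraction (>= 2).
#' @param seed integer seed.
#' @param n_coarse coarse lattice size for the fitter.
#' @return An object of class `"flim_study"` (kind `"low_fraction"`) with
#'   `conditions`, `replicates`, and `linear_fit_mean` / `linear_fit_mode`
#'   (slope, offset, 95% half-widths of the estimated-vs-prescribed OLS
#'   line).
#' @export
low_fraction_study <- function(short_master, long_master,
                               fractions = 2^-(1:10), n_total = 5e7,
                               n_reps = 100, seed = 1, n_coarse = 201) {
  stopifnot(inherits(short_master, "flim_master"),
            inherits(long_master, "flim_master"))
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly inside (0, 1)", call. = FALSE)
  if (n_reps < 2) stop("need at least 2 replicates", call. = FALSE)
  set.seed(as.integer(seed))
  ths <- short_master$theta
  engine <- fraction_fitter(short_master$irf, short_master$binning,
                            ths$tau_S, ths$tau_L, ths$T, n_coarse = n_coarse)
  fractions <- sort(fractions)
  reps <- vector("list", length(fractions))
  for (ci in seq_along(fractions)) {
    q <- fractions[ci]
    est <- matrix(NA_real_, n_reps, 2)
    for (r in seq_len(n_reps)) {
      h <- mix_masters(short_master, long_master, q, n_total)
      f <- tryCatch(engine(h), error = function(e) {
        warning(sprintf("fit failed at f=%g rep %d: %s", q, r,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(f)) next
      est[r, ] <- c(f$estimates$mean[f$estimates$parameter == "f_S"],
                    f$estimates$mode[f$estimates$parameter == "f_S"])
    }
    reps[[ci]] <- data.frame(fraction = q, rep = seq_len(n_reps),
                             est_mean = est[, 1], est_mode = est[, 2])
  }
  replicates <- do.call(rbind, reps)
  conditions <- summarize_conditions(replicates, "fraction", NULL)
  structure(list(kind = "low_fraction", conditions = conditions,
                 replicates = replicates, n_total = n_total,
                 n_reps = n_reps, seed = seed,
                 linear_fit_mean = ols_line(conditions$fraction,
                                            conditions$mean_est_mean),
                 linear_fit_mode = ols_line(conditions$fraction,
                                            conditions$mean_est_mode)),
            class = "flim_study")
}

#' Adjacent-difference (delta-fraction) analysis
#'
#' Changes in FRET fraction are often the quantity of interest, and an
#' additive estimation bias cancels in differences.  Takes the
#' per-condition mean estimates of a low-fraction study, forms differences
#' between adjacent prescribed fractions, and regresses estimated
#' differences on prescribed differences.
#'
#' @param study a [low_fraction_study()] result (>= 2 conditions).
#' @return An object of class `"flim_delta_study"`: `data` (prescribed and
#'   estimated differences) and `fit_mean` / `fit_mode` (slope, offset,
#'   95% half-widths).
#' @export
delta_fraction_study <- function(study) {
  stopifnot(inherits(study, "flim_study"))
  cond <- study$conditions
  if (!"fraction" %in% names(cond))
    stop("delta analysis needs a fraction-axis study", call. = FALSE)
  if (nrow(cond) < 2)
    stop("insufficient data: need at least 2 fraction conditions",
         call. = FALSE)
  cond <- cond[order(cond$fraction), ]
  d <- data.frame(d_prescribed = diff(cond$fraction),
                  d_est_mean = diff(cond$mean_est_mean),
                  d_est_mode = diff(cond$mean_est_mode))
  structure(list(data = d,
                 fit_mean = ols_line(d$d_prescribed, d$d_est_mean),
                 fit_mode = ols_line(d$d_prescribed, d$d_est_mode)),
            class = "flim_delta_study")
}

#' @export
print.flim_delta_study <- function(x, ...) {
  cat(sprintf("delta-fraction analysis over %d adjacent pairs\n",
              nrow(x$data)))
  cat(sprintf("  mean estimator: slope %.4f +/- %.4f, offset %.3g +/- %.3g\n",
              x$fit_mean$slope, x$fit_mean$ci_slope,
              x$fit_mean$offset, x$fit_mean$ci_offset))
  invisible(x)
}
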