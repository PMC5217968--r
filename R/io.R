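# Delimited-text readers/writers for histograms and IRFs, config loading,
# and a provenance hash.  All time units are nanoseconds.

# parse a 2-column (bin, value) delimited text file; header optional
read_two_column <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0) stop(sprintf("no data rows in %s", path), call. = FALSE)
  split_row <- function(s) strsplit(trimws(s), "[,;\t ]+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(lines[keep[1]])))
  if (anyNA(first)) keep <- keep[-1]  # header line
  if (length(keep) == 0) stop(sprintf("no data rows in %s", path), call. = FALSE)
  out <- matrix(NA_real_, length(keep), 2)
  for (k in seq_along(keep)) {
    f <- suppressWarnings(as.numeric(split_row(lines[keep[k]])))
    if (length(f) < 2 || anyNA(f[1:2]))
      stop(sprintf("parse error in %s at line %d: expected two numeric columns",
                   path, keep[k]), call. = FALSE)
    out[k, ] <- f[1:2]
  }
  list(bin = out[, 1], value = out[, 2], lines = keep)
}

#' Read a photon arrival histogram from delimited text
#'
#' Expects two columns `(bin_index, counts)`, comma/tab/space separated,
#' with an optional header line.  Counts must be non-negative integers;
#' violations are reported with the offending line number.
#'
#' @param path file path.
#' @param binning the [flim_binning()] the histogram lives on (its mask is
#'   applied to the result).
#' @return a [flim_histogram()].
#' @examples
#' acq <- default_acquisition()
#' h <- read_histogram(system.file("extdata", "synthetic_histogram.tsv",
#'                                 package = "flimbayes"), acq$binning)
#' h
#' @export
read_histogram <- function(path, binning) {
  stopifnot(inherits(binning, "flim_binning"))
  d <- read_two_column(path)
  bad <- which(d$value < 0)
  if (length(bad))
    stop(sprintf("validation error in %s at line %d: negative count",
                 path, d$lines[bad[1]]), call. = FALSE)
  bad <- which(abs(d$value - round(d$value)) > 1e-8)
  if (length(bad))
    stop(sprintf("validation error in %s at line %d: non-integer count",
                 path, d$lines[bad[1]]), call. = FALSE)
  counts <- numeric(binning$n_bins)
  idx <- round(d$bin)
  if (any(idx < 1 | idx > binning$n_bins))
    stop(sprintf("bin index out of range 1..%d in %s", binning$n_bins, path),
         call. = FALSE)
  counts[idx] <- d$value
  flim_histogram(counts, binning)
}

#' Write a histogram as delimited text
#'
#' @param hist a [flim_histogram()].
#' @param path output file path.
#' @param header write a `bin\\tcounts` header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path, header = TRUE) {
  stopifnot(inherits(hist, "flim_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("bin\tcounts", con)
  writeLines(sprintf("%d\t%d", seq_len(hist$binning$n_bins),
                     as.integer(hist$counts)), con)
  invisible(path)
}

#' Read a measured IRF from delimited text
#'
#' Two columns `(bin_index_or_time, counts)`.  If the file holds an
#' integer multiple of the target bin count, consecutive groups are summed
#' (edge-aligned aggregation) to rebin onto the acquisition grid.
#' Optionally subtracts a constant baseline estimated as the mean of a
#' pre-pulse bin range, clipping negatives to zero.  The result is
#' normalized to sum to 1.
#'
#' @param path file path.
#' @param binning target [flim_binning()].
#' @param baseline_bins optional integer vector of pre-pulse bin indices
#'   (on the file's grid) whose mean is subtracted; `NULL` (default) skips
#'   baseline subtraction.
#' @return a [flim_irf()].
#' @export
read_irf <- function(path, binning, baseline_bins = NULL) {
  stopifnot(inherits(binning, "flim_binning"))
  d <- read_two_column(path)
  w <- d$value
  if (any(w < 0))
    stop(sprintf("validation error in %s: negative IRF counts", path),
         call. = FALSE)
  if (!is.null(baseline_bins)) {
    w <- pmax(w - mean(w[baseline_bins]), 0)
  }
  n <- binning$n_bins
  if (length(w) != n) {
    if (length(w) %% n != 0)
      stop(sprintf("cannot rebin IRF of %d bins onto %d bins", length(w), n),
           call. = FALSE)
    k <- length(w) / n
    w <- colSums(matrix(w, nrow = k))
  }
  if (sum(w) <= 0)
    stop(sprintf("validation error in %s: IRF is all zero after processing",
                 path), call. = FALSE)
  flim_irf(w, binning)
}

#' Read a configuration file (YAML or JSON)
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Build acquisition objects from a configuration list
#'
#' Recognized keys: `n_bins`, `dt_ns` (or `window_ns`), `period_ns`,
#' `t0_ns`, `mask_low_bin`, `mask_high_bin`, `irf_path` or
#' `irf = list(center_ns, sigma_ns)`, `tau_S_ns`, `tau_L_ns`.
#' Unspecified values fall back to the default synthetic acquisition.
#'
#' @param cfg a named list, e.g. from [read_config()].
#' @return list with `binning`, `irf`, `period`, `tau_S`, `tau_L`.
#' @export
acquisition_from_config <- function(cfg) {
  n_bins <- cfg$n_bins %||% 256
  dt <- cfg$dt_ns %||% ((cfg$window_ns %||% 10) / n_bins)
  t0 <- cfg$t0_ns %||% 0
  mask <- window_mask(n_bins, cfg$mask_low_bin %||% 1,
                      cfg$mask_high_bin %||% n_bins)
  binning <- flim_binning(n_bins, dt, t0, mask)
  irf <- if (!is.null(cfg$irf_path)) {
    read_irf(cfg$irf_path, binning, cfg$irf_baseline_bins)
  } else {
    gaussian_irf(binning, center = cfg$irf$center_ns %||% 0.5,
                 sigma = cfg$irf$sigma_ns %||% 0.1)
  }
  list(binning = binning, irf = irf, period = cfg$period_ns %||% 12.5,
       tau_S = cfg$tau_S_ns %||% 0.48, tau_L = cfg$tau_L_ns %||% 4.03)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Provenance hash of a configuration
#'
#' A short stable hash (polynomial rolling hash modulo 2^31 - 1 over the
#' canonical JSON serialization) embedded in every output artifact so that
#' results can be traced to the configuration that produced them.
#'
#' @param cfg a named list.
#' @return an 8-character hex string.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a fit report as JSON
#'
#' Per-parameter marginal mean, mode, s.d. and 95% credible bounds, the
#' photon count, and an echo of the settings with the config hash.
#'
#' @param fit a [flim_fit()] object.
#' @param path output path (`.json`).
#' @param cfg optional configuration list to echo and hash.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, cfg = NULL) {
  stopifnot(inherits(fit, "flim_fit"))
  report <- list(
    parameters = fit$estimates,
    n_photons = fit$hist$n_photons,
    method = fit$method,
    settings = fit$settings,
    package_version = as.character(utils::packageVersion("flimbayes")))
  if (!is.null(cfg)) {
    report$config <- cfg
    report$config_hash <- config_hash(cfg)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
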