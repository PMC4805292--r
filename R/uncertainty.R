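# Decorrelation rule, bootstrap PMF uncertainty, convergence diagnostic.

#' Autocorrelation and the 1/e decorrelation lag
#'
#' Standard biased ACF estimate
#' \eqn{\rho(l) = \sum_t (z_t - \bar z)(z_{t+l} - \bar z) / \sum_t (z_t - \bar z)^2}
#' (as computed by [stats::acf()]), plus the decorrelation lag tau_e: the
#' smallest lag (in save-interval units) at which the ACF has fallen to 1/e,
#' inclusive -- rho(l) exactly equal to 1/e already counts. Samples spaced
#' tau_e apart are treated as effectively independent downstream.
#'
#' @param ts a `time_series` or numeric vector (production samples are used
#'   for a `time_series`).
#' @param max_lag largest lag to estimate (1 <= max_lag < series length).
#' @return a `decorrelation_report`: `acf` (lags 0..max_lag), `tau_e`, `n`.
#' @export
autocorrelation <- function(ts, max_lag) {
  z <- if (inherits(ts, "time_series")) production_samples(ts)
       else as.numeric(ts)
  stopifnot(max_lag >= 1, length(z) > max_lag)
  if (stats::var(z) == 0)
    stop("zero-variance series: autocorrelation is undefined")
  rho <- as.numeric(stats::acf(z, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)
  structure(list(acf = rho, tau_e = tau_from_acf(rho), n = length(z)),
            class = "decorrelation_report")
}

# smallest lag with rho(l) <= threshold (inclusive); max_lag + 1 if none --
# the conservative reading when the ACF never crosses within range
tau_from_acf <- function(rho, threshold = exp(-1)) {
  below <- which(rho[-1] <= threshold)
  if (length(below) == 0) length(rho) else below[1]
}

#' @export
print.decorrelation_report <- function(x, ...) {
  cat(sprintf(paste0("<decorrelation_report> n = %d; tau_e = %d save ",
                     "intervals (ACF there %.3f, threshold 1/e = %.3f)\n"),
              x$n, x$tau_e, x$acf[x$tau_e + 1], exp(-1)))
  invisible(x)
}

# decorrelation stride per window: ceil(tau_e) on the production samples
window_strides <- function(series, max_lag = 50) {
  vapply(series, function(ts) {
    z <- production_samples(ts)
    if (stats::var(z) == 0) return(1L) # constant series: trivially decorrelated
    ml <- min(max_lag, length(z) - 1)
    as.integer(ceiling(autocorrelation(z, ml)$tau_e))
  }, integer(1))
}

#' Bootstrap uncertainty of a WHAM PMF
#'
#' Generates `n_boot` pseudo-datasets from the original data with duplication
#' allowed: within each window, the decorrelated (tau_e-strided) production
#' samples are resampled with replacement to the original decorrelated count,
#' independently per window and per replicate. A PMF is reconstructed from
#' each pseudo-dataset; the pointwise standard deviation sigma(z) across
#' replicates (n-1 denominator, over replicates where the bin is finite) is
#' the profile's random error, and its maximum over finite bins, sigma_max,
#' is the single-number uncertainty reported for the profile.
#'
#' The resampling unit is the decorrelated sample, not the raw saved point:
#' resampling correlated points would understate the variance.
#'
#' @param series list of `time_series` with windows.
#' @param edges shared bin edges in Angstrom.
#' @param n_boot number of pseudo-datasets (default 10).
#' @param seed integer seed for the resampling RNG.
#' @param temperature,tol,max_iter passed to [solve_wham()].
#' @return a `bootstrap_result`: replicate-by-bin matrix `profiles` (bulk
#'   re-zeroed W, kT), `sigma`, `sigma_max`, per-window strides, and a
#'   `pmf_profile` of the full data with `sigma` attached.
#' @export
bootstrap_pmf <- function(series, edges, n_boot = 10, seed,
                          temperature = 298.15, tol = 1e-7, max_iter = 1e5) {
  stopifnot(n_boot >= 2)
  strides <- window_strides(series)
  decorr <- lapply(seq_along(series), function(i) {
    z <- production_samples(series[[i]])
    z[seq(1, length(z), by = strides[i])]
  })
  nkeep <- lengths(decorr)
  if (any(nkeep < 10))
    stop("each window needs >= 10 decorrelated samples for the bootstrap")
  decorr_series <- lapply(seq_along(series), function(i)
    new_time_series(decorr[[i]], series[[i]]$save_interval * strides[i],
                    window = series[[i]]$window))
  full <- solve_wham(build_histograms(decorr_series, edges),
                     temperature = temperature, tol = tol,
                     max_iter = max_iter)
  set.seed(seed)
  centers <- full$pmf$z
  profiles <- matrix(NA_real_, nrow = n_boot, ncol = length(centers))
  for (b in seq_len(n_boot)) {
    pseudo <- lapply(seq_along(series), function(i) {
      zi <- sample(decorr[[i]], nkeep[i], replace = TRUE)
      new_time_series(zi, series[[i]]$save_interval * strides[i],
                      window = series[[i]]$window)
    })
    sol <- tryCatch(
      solve_wham(build_histograms(pseudo, edges), temperature = temperature,
                 tol = tol, max_iter = max_iter),
      error = function(e) stop(sprintf("bootstrap replicate %d failed: %s",
                                       b, conditionMessage(e))))
    profiles[b, ] <- sol$pmf$W
  }
  sigma <- apply(profiles, 2, function(w) {
    w <- w[is.finite(w)]
    if (length(w) >= 2) stats::sd(w) else NA_real_
  })
  sigma_max <- max(sigma[is.finite(full$pmf$W) & !is.na(sigma)])
  pmf <- full$pmf
  pmf$sigma <- sigma
  structure(list(n_boot = n_boot, profiles = profiles, sigma = sigma,
                 sigma_max = sigma_max, seed = seed, strides = strides,
                 pmf = pmf),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_result> %d pseudo-datasets (seed %s); ",
                     "sigma_max = %.3f kT\n"),
              x$n_boot, format(x$seed), x$sigma_max))
  invisible(x)
}

#' Convergence of the PMF depth with simulation time
#'
#' Reconstructs the PMF from the first ceil(phi * N_i) production samples of
#' every window for each data fraction phi, and reports the profile depth
#' (minimum minus bulk value) per fraction plus the drift (maximum pairwise
#' depth difference). A converged calculation shows depths that do not drift
#' significantly as more data are included.
#'
#' @param series list of `time_series` with windows.
#' @param edges shared bin edges in Angstrom.
#' @param fractions strictly increasing data fractions in (0, 1], last = 1.
#' @param temperature,tol,max_iter passed to [solve_wham()].
#' @param stride histogram stride (decorrelation) applied after truncation.
#' @return a `convergence_report`: `fractions`, `depths` (kT), `drift` (kT).
#' @export
convergence_depths <- function(series, edges,
                               fractions = c(0.25, 0.5, 0.75, 1),
                               temperature = 298.15, tol = 1e-7,
                               max_iter = 1e5, stride = 1) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            all(diff(fractions) > 0),
            fractions[length(fractions)] == 1)
  depths <- vapply(fractions, function(phi) {
    trunc <- lapply(series, function(ts) {
      z <- production_samples(ts)
      keep <- ceiling(phi * length(z))
      if (keep == 0) stop("truncated window is empty")
      new_time_series(z[seq_len(keep)], ts$save_interval, window = ts$window)
    })
    sol <- solve_wham(build_histograms(trunc, edges, stride = stride),
                      temperature = temperature, tol = tol,
                      max_iter = max_iter)
    pmf_depth(sol$pmf)
  }, numeric(1))
  structure(list(fractions = fractions, depths = depths,
                 drift = max(depths) - min(depths)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report>\n")
  for (i in seq_along(x$fractions))
    cat(sprintf("  %.0f%% of data: depth %.3f kT\n",
                100 * x$fractions[i], x$depths[i]))
  cat(sprintf("  drift (max pairwise difference): %.3f kT\n", x$drift))
  invisible(x)
}
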