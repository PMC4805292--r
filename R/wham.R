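# WHAM: self-consistent reconstruction of the unbiased probability profile
# from biased window histograms, and the PMF container built from it.

#' Bin umbrella-window timeseries into a histogram set
#'
#' Every `stride`-th production (post burn-in) sample of every window is
#' binned on a shared regular grid with the half-open convention [lo, hi):
#' a value exactly at the last edge is dropped. Out-of-range samples are
#' dropped and counted per window. Striding implements decorrelated saving:
#' pass the 1/e lag from [autocorrelation()] to retain approximately
#' independent points.
#'
#' @param series list of `time_series`, each carrying its `umbrella_window`.
#' @param edges strictly increasing, regularly spaced bin edges in Angstrom.
#' @param stride keep every `stride`-th retained sample (>= 1).
#' @return a `histogram_set`: edges, bin centers, the window-by-bin count
#'   matrix, per-window retained totals `N` and dropped counts.
#' @export
build_histograms <- function(series, edges, stride = 1) {
  stopifnot(is.list(series), length(series) >= 1,
            length(edges) >= 2, all(diff(edges) > 0), stride >= 1)
  stride <- as.integer(stride)
  windows <- lapply(series, function(ts) ts$window)
  if (any(vapply(windows, is.null, TRUE)))
    stop("every timeseries must reference an umbrella window")
  nb <- length(edges) - 1
  width <- edges[2] - edges[1]
  counts <- matrix(0, nrow = length(series), ncol = nb)
  N <- integer(length(series)); dropped <- integer(length(series))
  for (i in seq_along(series)) {
    z <- production_samples(series[[i]])
    z <- z[seq(1, length(z), by = stride)]
    idx <- floor((z - edges[1]) / width) + 1
    inside <- z >= edges[1] & z < edges[nb + 1]
    dropped[i] <- sum(!inside)
    idx <- idx[inside]
    if (length(idx) == 0)
      stop(sprintf("window %d (%s): zero retained samples in range",
                   i, windows[[i]]$label))
    counts[i, ] <- tabulate(idx, nbins = nb)
    N[i] <- length(idx)
  }
  structure(list(edges = edges, centers = (edges[-1] + edges[-(nb + 1)]) / 2,
                 counts = counts, N = N, dropped = dropped,
                 windows = windows),
            class = "histogram_set")
}

#' @export
print.histogram_set <- function(x, ...) {
  cat(sprintf("<histogram_set> %d windows x %d bins on [%.4g, %.4g] A\n",
              nrow(x$counts), ncol(x$counts), x$edges[1],
              x$edges[length(x$edges)]))
  cat("  retained per window:", paste(x$N, collapse = " "), "\n")
  invisible(x)
}

#' Solve the WHAM equations
#'
#' Direct self-consistent iteration of
#' \deqn{P_j = \frac{\sum_i n_{ij}}{\sum_i N_i \exp[(f_i - c_{ij})/kT]},
#'   \qquad e^{-f_i/kT} = \sum_j P_j e^{-c_{ij}/kT},}
#' with \eqn{c_{ij}} the harmonic bias energy of window i at bin center j
#' (all energies in kT, so kT = 1 internally). Iteration stops when
#' \eqn{\max_i |\Delta f_i| \le} `tol`, with the gauge f_1 = 0. The PMF is
#' \eqn{W_j = -kT \ln P_j}, re-zeroed to the requested convention; bins with
#' zero total count carry W = +Inf and are excluded from integration
#' downstream.
#'
#' @param h a `histogram_set`.
#' @param windows optional list of `umbrella_window`s (defaults to those
#'   carried by `h`; must align 1:1 with histogram rows).
#' @param temperature temperature in K (recorded; energies are already kT).
#' @param tol convergence tolerance on the window free energies, kT.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   final residual.
#' @param convention zero convention passed to [rezero_pmf()].
#' @return list with `pmf` (a `pmf_profile`) and `free_energies` (a
#'   `window_free_energies`: f in kT with f_1 = 0, iterations, final
#'   residual, residual trace).
#' @export
solve_wham <- function(h, windows = NULL, temperature = 298.15, tol = 1e-7,
                       max_iter = 1e5, convention = "bulk") {
  stopifnot(inherits(h, "histogram_set"))
  windows <- windows %||% h$windows
  if (length(windows) != nrow(h$counts))
    stop("windows must align 1:1 with histogram rows")
  if (all(h$counts == 0)) stop("all histogram bins are empty")
  bias <- t(vapply(windows, function(w) harmonic_bias_energy(w, h$centers),
                   numeric(length(h$centers))))
  sol <- .wham_cpp(h$counts, bias, as.numeric(h$N), tol, as.integer(max_iter))
  if (!sol$converged)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kT)",
                 as.integer(max_iter), sol$residual))
  pmf <- new_pmf_profile(h$centers, sol$W, sigma = NULL,
                         temperature = temperature)
  pmf <- rezero_pmf(pmf, convention)
  fe <- structure(list(f = sol$f, iterations = sol$iterations,
                       residual = sol$residual, converged = sol$converged,
                       residual_trace = sol$residual_trace),
                  class = "window_free_energies")
  list(pmf = pmf, free_energies = fe)
}

#' @export
print.window_free_energies <- function(x, ...) {
  cat(sprintf(paste0("<window_free_energies> %d windows, converged in %d ",
                     "iterations (residual %.3g kT)\n"),
              length(x$f), x$iterations, x$residual))
  invisible(x)
}

new_pmf_profile <- function(z, W, sigma = NULL, convention = "none",
                            temperature = 298.15) {
  stopifnot(length(z) == length(W))
  if (!is.null(sigma)) stopifnot(length(sigma) == length(W),
                                 all(sigma >= 0 | !is.finite(sigma)))
  structure(list(z = as.numeric(z), W = as.numeric(W), sigma = sigma,
                 convention = convention, temperature = temperature,
                 z_range = range(z)),
            class = "pmf_profile")
}

#' Construct a PMF profile from tabulated values
#'
#' Builds a `pmf_profile` directly (e.g. from a ground-truth potential
#' evaluated on bin centers, or from a file) without running WHAM.
#'
#' @param z bin centers in Angstrom (increasing).
#' @param W free energies in kT (+Inf marks unsampled bins).
#' @param sigma optional pointwise uncertainties in kT.
#' @param convention zero convention already applied ("bulk", "min", "none").
#' @param temperature temperature in K.
#' @export
pmf_profile <- function(z, W, sigma = NULL, convention = "none",
                        temperature = 298.15) {
  stopifnot(all(diff(z) > 0))
  new_pmf_profile(z, W, sigma, convention, temperature)
}

#' @export
print.pmf_profile <- function(x, ...) {
  fin <- is.finite(x$W)
  cat(sprintf("<pmf_profile> %d bins on [%.4g, %.4g] A (%d unsampled)\n",
              length(x$z), x$z_range[1], x$z_range[2], sum(!fin)))
  if (any(fin))
    cat(sprintf("  depth (min - bulk): %.3f kT; zero convention: %s\n",
                pmf_depth(x), x$convention))
  if (!is.null(x$sigma))
    cat(sprintf("  max pointwise uncertainty: %.3f kT\n",
                max(x$sigma[is.finite(x$sigma)])))
  invisible(x)
}

#' Re-zero a PMF profile
#'
#' `bulk`: subtract W at the largest-z finite bin (profiles approach zero in
#' the bulk); `min`: subtract the minimum so the well bottom sits at zero.
#' Idempotent under repetition.
#'
#' @param p a `pmf_profile` with at least one finite bin.
#' @param convention `"bulk"` or `"min"`.
#' @export
rezero_pmf <- function(p, convention = c("bulk", "min")) {
  convention <- match.arg(convention)
  fin <- which(is.finite(p$W))
  if (length(fin) == 0) stop("profile has no finite bins")
  ref <- switch(convention,
                bulk = p$W[fin[length(fin)]],
                min = min(p$W[fin]))
  p$W <- p$W - ref
  p$convention <- convention
  p
}

# profile depth: min(W) minus W at the bulk-side (largest-z) finite bin
pmf_depth <- function(p) {
  fin <- which(is.finite(p$W))
  min(p$W[fin]) - p$W[fin[length(fin)]]
}
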