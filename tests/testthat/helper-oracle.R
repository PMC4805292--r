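# Independent brute-force WHAM oracle: naive fixed-point iteration of the two
# self-consistency equations in plain R, starting from f = 0, run to (near)
# machine precision. Deliberately shares no code path with the package solver
# (no probability renormalisation, scalar loops, plain exp).
wham_oracle <- function(counts, bias, N, tol = 1e-13, max_iter = 2e6) {
  nw <- nrow(counts); nb <- ncol(counts)
  Cj <- colSums(counts)
  f <- rep(0, nw)
  for (it in seq_len(max_iter)) {
    P <- numeric(nb)
    for (j in seq_len(nb)) {
      denom <- 0
      for (i in seq_len(nw)) denom <- denom + N[i] * exp(f[i] - bias[i, j])
      P[j] <- if (denom > 0) Cj[j] / denom else 0
    }
    fnew <- numeric(nw)
    for (i in seq_len(nw)) {
      Z <- 0
      for (j in seq_len(nb)) Z <- Z + P[j] * exp(-bias[i, j])
      fnew[i] <- -log(Z)
    }
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid <= tol) break
  }
  W <- ifelse(P > 0, -log(P), Inf)
  list(f = f, W = W, P = P, iterations = it, residual = resid)
}

# bulk re-zero a raw W vector (subtract value at the largest finite index)
rezero_bulk <- function(W) {
  fin <- which(is.finite(W))
  W - W[fin[length(fin)]]
}

# bias matrix (windows x bins) for half-k harmonic windows
bias_matrix <- function(centers, springs, bin_centers) {
  t(vapply(seq_along(centers),
           function(i) 0.5 * springs[i] * (bin_centers - centers[i])^2,
           numeric(length(bin_centers))))
}

# wrap a counts/bias fixture as a histogram_set + window list for solve_wham
as_histogram_set <- function(counts, edges, centers, springs) {
  windows <- lapply(seq_along(centers),
                    function(i) umbrella_window(centers[i], springs[i]))
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, N = rowSums(counts),
                 dropped = rep(0L, nrow(counts)), windows = windows),
            class = "histogram_set")
}
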