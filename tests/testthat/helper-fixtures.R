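# Shared synthetic fixtures and the chi-square Boltzmann check.

flat_potential <- function() square_well_potential(0, 1)

# the canonical binding study conditions: 12 windows on 8..30 A, spacing 2 A,
# k_s = 4 kT/A^2, samples saved every 1 ps
binding_window_set <- function(n_production, seed, spring = 4,
                               burnin_frac = 0.1) {
  n_save <- ceiling(n_production / (1 - burnin_frac))
  cfg <- sim_config(seed = seed, n_steps = n_save * 200, dt = 0.005,
                    s_save = 200, burnin_frac = burnin_frac)
  generate_window_set(example_binding_potential(), 8, 30, 2, spring, cfg)
}

binding_edges <- function() seq(6.75, 30.25, by = 0.5)

# truth PMF on the same bin centers, bulk re-zeroed
binding_truth_profile <- function(edges = binding_edges()) {
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  W <- evaluate_potential(example_binding_potential(), centers)
  pmf_profile(centers, W - W[length(W)], convention = "bulk")
}

# chi-square goodness of fit of decorrelated samples against the Boltzmann
# distribution of truth + bias. Samples are subsampled at the lag where the
# ACF falls to 0.02 so the multinomial independence assumption holds; bins
# with expected count < 10 are excluded (conditional multinomial).
boltzmann_chisq <- function(truth, window, seed, edges, n_save = 5.6e5) {
  cfg <- sim_config(seed = seed, n_steps = n_save * 100, dt = 0.005,
                    s_save = 100)
  ts <- simulate_window(truth, window, cfg)
  z <- production_samples(ts)
  stride <- pmfkd:::tau_from_acf(autocorrelation(ts, 30)$acf, 0.02)
  zd <- z[seq(1, length(z), by = stride)]
  U <- function(x) evaluate_potential(truth, x) +
    if (!is.null(window)) harmonic_bias_energy(window, x) else 0
  nb <- length(edges) - 1
  pexp <- vapply(seq_len(nb), function(j)
    stats::integrate(function(x) exp(-U(x)), edges[j], edges[j + 1])$value,
    numeric(1))
  pexp <- pexp / sum(pexp)
  inside <- zd >= edges[1] & zd < edges[nb + 1]
  counts <- tabulate(findInterval(zd[inside], edges), nbins = nb)
  keep <- length(zd[inside]) * pexp >= 10
  suppressWarnings(
    stats::chisq.test(counts[keep], p = pexp[keep], rescale.p = TRUE))
}
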