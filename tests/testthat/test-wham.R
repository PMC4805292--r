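make_series <- function(z, center, spring, dt = 1) {
  ts <- pmfkd:::new_time_series(z, save_interval = dt,
                                window = umbrella_window(center, spring))
  ts
}

test_that("histogram binning follows the half-open stride-aware contract", {
  ts <- make_series(rep(0.25, 100), 0, 1)
  h <- build_histograms(list(ts), edges = seq(0, 1, 0.5))
  expect_equal(h$counts[1, ], c(100, 0))
  expect_equal(h$N, 100L)

  h2 <- build_histograms(list(ts), edges = seq(0, 1, 0.5), stride = 2)
  expect_equal(h2$N, 50L)

  # a value exactly at the last edge is dropped (half-open bins)
  ts3 <- make_series(c(0.2, 1.0), 0, 1)
  h3 <- build_histograms(list(ts3), edges = seq(0, 1, 0.5))
  expect_equal(h3$N, 1L)
  expect_equal(h3$dropped, 1L)

  # a window with no in-range samples errors, naming the window
  far <- make_series(rep(5, 10), 5, 1)
  expect_error(build_histograms(list(far), edges = seq(0, 1, 0.5)),
               "window 1")
})

test_that("single-window WHAM degenerates to Boltzmann inversion", {
  set.seed(1)
  z <- rnorm(4000, 0.5, 0.2)
  ts <- make_series(z, 0.5, 1e-12)  # negligible bias
  h <- build_histograms(list(ts), edges = seq(-0.25, 1.25, 0.25))
  sol <- solve_wham(h, tol = 1e-13)
  ref <- rezero_bulk(-log(h$counts[1, ] / h$N))
  expect_lt(max(abs(sol$pmf$W - ref)), 1e-10)
})

test_that("duplicating a window leaves the PMF unchanged", {
  set.seed(2)
  z <- rnorm(2000, 1, 0.5)
  ts <- make_series(z, 1, 2)
  edges <- seq(-1, 3, 0.4)
  one <- solve_wham(build_histograms(list(ts), edges), tol = 1e-12)
  two <- solve_wham(build_histograms(list(ts, ts), edges), tol = 1e-12)
  expect_equal(two$pmf$W, one$pmf$W, tolerance = 1e-9)
})

test_that("solver matches the brute-force oracle on toy fixtures", {
  # hand-fixed two-window, five-bin instance
  counts <- rbind(c(40, 30, 20, 8, 2),
                  c(2, 10, 25, 35, 28))
  edges <- seq(0, 2.5, 0.5)
  centers_w <- c(0.5, 2.0); springs <- c(3, 3)
  h <- as_histogram_set(counts, edges, centers_w, springs)
  sol <- solve_wham(h, tol = 1e-12)
  bias <- bias_matrix(centers_w, springs, h$centers)
  ora <- wham_oracle(counts, bias, rowSums(counts))
  expect_lt(max(abs(sol$pmf$W - rezero_bulk(ora$W))), 1e-8)
  expect_lt(max(abs(sol$free_energies$f - ora$f)), 1e-8)
})

test_that("estimator is invariant under window order and coordinate shifts", {
  series <- binding_window_set(800, seed = 31)[1:3]  # centers 8, 10, 12
  edges <- seq(6.75, 13.25, 0.5)
  base <- solve_wham(build_histograms(series, edges), tol = 1e-10,
                     max_iter = 1e6)
  perm <- solve_wham(build_histograms(rev(series), edges), tol = 1e-10,
                     max_iter = 1e6)
  expect_equal(perm$pmf$W, base$pmf$W, tolerance = 1e-8)

  shift <- 4.25
  shifted <- lapply(series, function(ts) {
    w <- umbrella_window(ts$window$center + shift, ts$window$spring)
    pmfkd:::new_time_series(ts$z + shift, ts$save_interval, window = w,
                            n_burnin = ts$n_burnin)
  })
  sh <- solve_wham(build_histograms(shifted, edges + shift), tol = 1e-10,
                   max_iter = 1e6)
  expect_equal(sh$pmf$W, base$pmf$W, tolerance = 1e-8)
  expect_equal(sh$pmf$z, base$pmf$z + shift)
})

test_that("residual decreases monotonically after the early transient", {
  # 2-window fixtures: monotone after the first iterations
  counts <- rbind(c(40, 30, 20, 8, 2), c(2, 10, 25, 35, 28))
  h <- as_histogram_set(counts, seq(0, 2.5, 0.5), c(0.5, 2), c(3, 3))
  tr <- solve_wham(h, tol = 1e-12)$free_energies$residual_trace
  expect_true(all(diff(tr[-(1:10)]) <= 0))
  # 12-window set: information propagates across windows for ~20 sweeps
  # before the residual settles into monotone decay
  series <- binding_window_set(500, seed = 33)
  tr2 <- solve_wham(build_histograms(series,
                                     binding_edges()))$free_energies$residual_trace
  expect_true(all(diff(tr2[-(1:30)]) <= 0))
})

test_that("non-convergence and empty histograms are errors", {
  series <- binding_window_set(300, seed = 35)
  h <- build_histograms(series, binding_edges())
  expect_error(solve_wham(h, max_iter = 2), "did not converge")
  h0 <- h; h0$counts[] <- 0
  expect_error(solve_wham(h0), "empty")
})

test_that("re-zeroing conventions behave and are idempotent", {
  p <- pmf_profile(1:5, c(Inf, 2, -1, 0.5, 1))
  pb <- rezero_pmf(p, "bulk")
  expect_equal(pb$W, c(Inf, 1, -2, -0.5, 0))
  expect_equal(rezero_pmf(pb, "bulk")$W, pb$W)   # idempotent
  pm <- rezero_pmf(p, "min")
  expect_equal(min(pm$W[is.finite(pm$W)]), 0)
  const <- rezero_pmf(pmf_profile(1:4, rep(3, 4)), "bulk")
  expect_equal(const$W, rep(0, 4))
})

test_that("WHAM recovers a known double-well profile from umbrella data", {
  # reduced-scale companion of the acceptance-scale recovery check
  series <- binding_window_set(5000, seed = 40)
  h <- build_histograms(series, binding_edges())
  sol <- solve_wham(h)
  truth <- binding_truth_profile()
  well <- colSums(h$counts) >= 100
  rmse <- sqrt(mean((sol$pmf$W[well] - truth$W[well])^2))
  expect_lt(rmse, 0.5)
})
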