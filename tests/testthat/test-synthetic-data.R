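test_that("free diffusion obeys the 2*D*t displacement law", {
  cfg <- sim_config(seed = 3, n_steps = 2e5, dt = 0.01, D = 1, s_save = 20,
                    burnin_frac = 0)
  ts <- simulate_window(flat_potential(), NULL, cfg)
  d <- diff(ts$z)  # displacements over m = 20 steps are iid N(0, 2*D*m*dt)
  v_true <- 2 * 1 * 20 * 0.01
  n <- length(d)
  expect_lt(abs(mean(d)), 4 * sqrt(v_true / n))
  expect_lt(abs(stats::var(d) - v_true), 4 * v_true * sqrt(2 / (n - 1)))
})

test_that("a harmonic bias alone reaches the Boltzmann variance kT/k", {
  w <- umbrella_window(5, 1)
  cfg <- sim_config(seed = 4, n_steps = 2e5 * 100, dt = 0.005, s_save = 100)
  z <- production_samples(simulate_window(flat_potential(), w, cfg))
  expect_lt(abs(mean(z) - 5), 0.02)
  expect_lt(abs(stats::var(z) - 1), 0.05)
})

test_that("unstable timestep is rejected before any stepping", {
  w <- umbrella_window(0, 30)
  cfg <- sim_config(seed = 1, n_steps = 1000, dt = 0.005, s_save = 10)
  expect_error(simulate_window(flat_potential(), w, cfg), "unstable")
  # stiffness of the truth counts toward k_max too
  cfg2 <- sim_config(seed = 1, n_steps = 1000, dt = 0.05, s_save = 10)
  expect_error(simulate_window(harmonic_potential(3), NULL, cfg2), "unstable")
})

test_that("window sets are regular grids with reproducible streams", {
  cfg <- sim_config(seed = 10, n_steps = 4000, dt = 0.005, s_save = 20)
  s1 <- generate_window_set(flat_potential(), 0, 10, 1, 10, cfg)
  expect_length(s1, 11)
  expect_equal(vapply(s1, function(ts) ts$window$center, numeric(1)), 0:10)
  s2 <- generate_window_set(flat_potential(), 0, 10, 1, 10, cfg)
  expect_identical(lapply(s1, `[[`, "z"), lapply(s2, `[[`, "z"))
  # different windows use different streams
  expect_false(identical(s1[[1]]$z - 0, s1[[2]]$z - 1))
})

test_that("window sample means sit on the centers for a flat truth", {
  cfg <- sim_config(seed = 12, n_steps = 5e3 * 50, dt = 0.005, s_save = 50)
  series <- generate_window_set(flat_potential(), 0, 4, 1, 10, cfg)
  for (ts in series) {
    z <- production_samples(ts)
    # sd(mean) for correlated samples; saved points here are near-independent
    se <- stats::sd(z) / sqrt(length(z) / 2)
    expect_lt(abs(mean(z) - ts$window$center), 3 * se)
  }
})

test_that("poorly overlapping windows trigger the overlap warning", {
  cfg <- sim_config(seed = 13, n_steps = 2000 * 10, dt = 0.002, s_save = 10)
  w <- capture_warnings(generate_window_set(flat_potential(), 0, 12, 6, 20,
                                            cfg))
  expect_true(all(grepl("overlap", w)))
  expect_length(w, 2)  # both adjacent pairs fail to overlap
})

test_that("stiffer springs decorrelate faster (3-point ladder)", {
  taus <- vapply(c(0.5, 2, 8), function(k) {
    cfg <- sim_config(seed = 6, n_steps = 5e4 * 10, dt = 0.005, s_save = 10)
    autocorrelation(simulate_window(flat_potential(),
                                    umbrella_window(0, k), cfg), 200)$tau_e
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("burn-in flags the first 10% of saved samples by default", {
  cfg <- sim_config(seed = 2, n_steps = 1000, dt = 0.01, s_save = 10)
  ts <- simulate_window(flat_potential(), umbrella_window(0, 5), cfg)
  expect_length(ts$z, 100)
  expect_equal(ts$n_burnin, 10L)
  expect_length(production_samples(ts), 90)
})

test_that("scheduled pulls confine the coordinate after the ramp", {
  r <- flat_bottom_restraint(stiffness = 10,
                             schedule = list(b_start = 12, b_end = 3,
                                             t_ramp = 50))
  cfg <- sim_config(seed = 5, n_steps = 200 * 200, dt = 0.005, s_save = 200,
                    z_init = 11, burnin_frac = 0)
  ts <- simulate_pull(flat_potential(), r, cfg)
  post <- ts$z[(50 / ts$save_interval + 1):length(ts$z)]
  expect_lt(mean(post > 3 + 3 * sqrt(1 / 10)), 0.01)
  expect_error(simulate_pull(flat_potential(),
                             flat_bottom_restraint(bound = 3), cfg),
               "schedule")
})

test_that("a never-engaging restraint reproduces the unrestrained run", {
  truth <- harmonic_potential(1, 0)  # confines |z| well below 10
  r <- flat_bottom_restraint(stiffness = 10,
                             schedule = list(b_start = 10, b_end = 10,
                                             t_ramp = 5))
  cfg <- sim_config(seed = 9, n_steps = 5000, dt = 0.005, s_save = 10)
  expect_identical(simulate_pull(truth, r, cfg)$z,
                   simulate_window(truth, NULL, cfg)$z)
})

test_that("sampling matches the Boltzmann distribution of truth + bias", {
  # lighter companion of the acceptance-scale chi-square: harmonic fixture
  ct <- boltzmann_chisq(harmonic_potential(1, 0), umbrella_window(1, 1),
                        seed = 77,
                        edges = seq(0.5 - 4 * sqrt(0.5), 0.5 + 4 * sqrt(0.5),
                                    length.out = 25),
                        n_save = 1e5)
  expect_gt(ct$p.value, 0.01)
})
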