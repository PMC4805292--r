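NA_CONST <- 6.02214076e23

test_that("flat-profile Kd matches the closed form and the SI unit chain", {
  z <- seq(0, 10, 0.5)
  p <- pmf_profile(z, rep(0, length(z)), convention = "bulk")
  res <- compute_kd(p, radius = 8)
  kd_inv_hand <- pi * 8^2 * 10 * 1e-27 * NA_CONST   # ~1.21 L/mol
  expect_equal(res$kd_inv, kd_inv_hand, tolerance = 1e-12)
  expect_equal(res$kd, 1 / kd_inv_hand, tolerance = 1e-12)
  # the textbook SI form 1000 * pi * R^2 * N_A * Integral (metres) is the
  # same number as the Angstrom pipeline with the 1e-27 L/A^3 factor
  R_m <- 8e-10; I_m <- 10e-10
  expect_equal(1000 * pi * R_m^2 * NA_CONST * I_m, kd_inv_hand,
               tolerance = 1e-12)
})

test_that("square-well Kd matches the hand-derived piecewise integral", {
  z <- seq(0, 10, 0.01)
  W <- ifelse(z <= 2, -10, 0)
  res <- compute_kd(pmf_profile(z, W, convention = "bulk"), radius = 8)
  hand <- pi * 64 * 1e-27 * NA_CONST * (2 * exp(10) + 8)
  expect_lt(abs(res$kd_inv - hand) / hand, 0.005)
})

test_that("degenerate ranges follow the documented contract", {
  p <- pmf_profile(seq(0, 10, 0.5), rep(0, 21), convention = "bulk")
  expect_equal(compute_kd(p, z_min = 4, z_max = 4)$kd, Inf)  # I = 0
  expect_error(compute_kd(p, z_min = 5, z_max = 4), "z_min")
  # unsampled bins inside the range are excluded with a warning
  p2 <- pmf_profile(seq(0, 10, 0.5), c(rep(0, 10), Inf, rep(0, 10)),
                    convention = "bulk")
  expect_warning(compute_kd(p2), "unsampled")
})

test_that("deeper wells bind tighter and bulk truncation is exactly linear", {
  z <- seq(0, 20, 0.25)
  kd_at_depth <- function(d) {
    W <- -d * exp(-0.5 * ((z - 5) / 1)^2)
    compute_kd(pmf_profile(z, W, convention = "bulk"))$kd
  }
  kds <- vapply(c(2, 4, 6, 8), kd_at_depth, numeric(1))
  expect_true(all(diff(kds) < 0))
  # truncating flat bulk shortens the integral by exactly the cut length
  flat <- pmf_profile(z, rep(0, length(z)), convention = "bulk")
  a <- compute_kd(flat, z_min = 0, z_max = 20)
  b <- compute_kd(flat, z_min = 0, z_max = 14)
  expect_equal(a$kd_inv - b$kd_inv, pi * 64 * 6 * 1e-27 * NA_CONST,
               tolerance = 1e-10)
})

test_that("halving the bin width moves Kd by less than 0.5%", {
  truth <- example_binding_potential()
  kd_at <- function(dz) {
    z <- seq(7, 31, dz)
    W <- evaluate_potential(truth, z)
    compute_kd(pmf_profile(z, W - W[length(W)], convention = "bulk"))$kd
  }
  expect_lt(abs(kd_at(0.25) / kd_at(0.5) - 1), 0.005)
})

test_that("uncertainty bounds factor e^sigma out of the integral", {
  z <- seq(0, 10, 0.5)
  p <- pmf_profile(z, rep(0, 21), convention = "bulk")
  b0 <- kd_bounds(p, sigma_max = 0)
  expect_equal(b0$kd_low, b0$kd)
  expect_equal(b0$kd_high, b0$kd)
  b1 <- kd_bounds(p, sigma_max = 1)
  expect_equal(b1$kd_high / b1$kd, exp(1), tolerance = 1e-10)
  expect_equal(b1$kd / b1$kd_low, exp(1), tolerance = 1e-10)
  # ordering holds for an arbitrary profile
  set.seed(5)
  q <- pmf_profile(z, rnorm(21), convention = "bulk")
  bq <- kd_bounds(q, sigma_max = 0.4)
  expect_true(bq$kd_low <= bq$kd && bq$kd <= bq$kd_high)
})

test_that("single-site block fraction follows C/(C+Kd)", {
  expect_equal(fraction_blocked(2e-6, 2e-6), 0.5)
  expect_equal(fraction_blocked(0, 1e-6), 0)
  expect_equal(fraction_blocked(9e-6, 1e-6), 0.9)
  expect_error(fraction_blocked(-1, 1))
})
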