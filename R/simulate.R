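# Synthetic umbrella-sampling data: overdamped Langevin (Euler-Maruyama)
# trajectories in a known ground-truth potential plus window bias, saved at a
# fixed stride. Stands in for cluster-scale biased MD so every estimator in
# the package can be validated against exact references.

#' Simulation configuration
#'
#' Parameters of the overdamped Langevin generator. Defaults mirror common
#' umbrella-sampling practice: samples saved every 1 ps (dt = 0.005 ps,
#' stride 200 steps), chosen so successive saved points of a typical window
#' are decorrelated to about 1/e or better.
#'
#' @param seed integer RNG seed (required; every trajectory is bitwise
#'   reproducible given the seed).
#' @param n_steps total integration steps.
#' @param dt timestep in ps.
#' @param D diffusion coefficient in A^2/ps.
#' @param s_save save stride in steps (one sample per `s_save` steps).
#' @param temperature temperature in K (energies are internally in kT; the
#'   temperature is carried for unit conversion at I/O boundaries).
#' @param z_init initial position in Angstrom; defaults to the window center
#'   when simulating a window, else 0.
#' @param burnin_frac fraction of *saved* samples flagged as equilibration and
#'   excluded by default downstream (histograms, bootstrap, convergence).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed, n_steps, dt = 0.005, D = 1, s_save = 200,
                       temperature = 298.15, z_init = NULL,
                       burnin_frac = 0.1) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed),
            D > 0, dt > 0, n_steps >= s_save, s_save >= 1,
            burnin_frac >= 0, burnin_frac < 1)
  structure(list(seed = as.integer(seed), n_steps = n_steps, dt = dt, D = D,
                 s_save = as.integer(s_save), temperature = temperature,
                 z_init = z_init, burnin_frac = burnin_frac),
            class = "sim_config")
}

# dt * D * k_max must stay well below 1 for Euler-Maruyama stability; the
# configuration contract demands < 0.1 (checked before any stepping).
check_stability <- function(cfg, k_max) {
  s <- cfg$dt * cfg$D * k_max
  if (s >= 0.1)
    stop(sprintf(paste0("unstable configuration: dt*D*k_max = %.3g >= 0.1 ",
                        "(k_max = %.3g kT/A^2); reduce dt"), s, k_max))
  invisible(s)
}

new_time_series <- function(z, save_interval, window = NULL, seed = NA,
                            n_burnin = 0L) {
  stopifnot(length(z) >= 1, all(is.finite(z)))
  structure(list(z = as.numeric(z), save_interval = save_interval,
                 window = window, seed = seed, n_burnin = as.integer(n_burnin)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  lab <- if (is.null(x$window)) "unbiased" else x$window$label
  cat(sprintf(paste0("<time_series> %s: %d samples (%d equilibration), ",
                     "saved every %.4g ps\n"),
              lab, length(x$z), x$n_burnin, x$save_interval))
  invisible(x)
}

#' Production samples of a timeseries
#'
#' Drops the leading equilibration (burn-in) samples flagged at generation
#' time. File-loaded series carry no burn-in flag and are returned whole.
#'
#' @param ts a `time_series`.
#' @export
production_samples <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  if (ts$n_burnin > 0) ts$z[-seq_len(ts$n_burnin)] else ts$z
}

# shared driver around the compiled integrator
run_langevin <- function(truth, cfg, window = NULL, restraint = NULL) {
  stopifnot(inherits(truth, "potential_1d"), inherits(cfg, "sim_config"))
  k_max <- potential_max_stiffness(truth) +
    (if (!is.null(window)) window$spring else 0) +
    (if (!is.null(restraint)) restraint$stiffness else 0)
  check_stability(cfg, k_max)
  z0 <- cfg$z_init %||% (if (!is.null(window)) window$center else 0)
  if (z0 < truth$domain[1] || z0 > truth$domain[2])
    stop("initial position outside the potential domain")
  kind <- match(truth$kind, c("square_well", "harmonic", "double_well",
                              "tabulated")) - 1L
  par <- switch(truth$kind,
    square_well = 0,
    harmonic = c(truth$params$stiffness, truth$params$center),
    double_well = as.numeric(rbind(truth$params$depth, truth$params$center,
                                   truth$params$width)),
    tabulated = 0)
  grid <- if (truth$kind == "tabulated") tabulated_force_grid(truth)
          else list(z = 0, F = 0)
  sched <- if (!is.null(restraint)) {
    s <- restraint$schedule %||% list(b_start = restraint$bound,
                                      b_end = restraint$bound, t_ramp = 0)
    c(restraint$stiffness, s$b_start, s$b_end, s$t_ramp)
  } else c(0, 0, 0, 0)
  set.seed(cfg$seed)
  z <- .langevin_cpp(kind, par, grid$z, grid$F,
                     !is.null(window),
                     if (!is.null(window)) window$spring else 0,
                     if (!is.null(window)) window$center else 0,
                     !is.null(restraint), sched[1], sched[2], sched[3],
                     sched[4],
                     cfg$D, cfg$dt, cfg$n_steps, cfg$s_save, z0,
                     truth$domain[1], truth$domain[2])
  new_time_series(z, save_interval = cfg$dt * cfg$s_save, window = window,
                  seed = cfg$seed,
                  n_burnin = floor(cfg$burnin_frac * length(z)))
}

#' Simulate one umbrella window
#'
#' Euler-Maruyama overdamped Langevin dynamics in the combined potential
#' (ground truth + optional harmonic window bias):
#' \deqn{z \leftarrow z - D\,dt\,\partial_z(U + bias)/kT + \sqrt{2 D dt}\,\xi,
#'       \quad \xi \sim N(0,1),}
#' recorded every `s_save` steps. The stationary distribution converges to the
#' Boltzmann distribution of the combined potential in the small-dt limit; the
#' configuration is rejected before stepping if dt*D*k_max >= 0.1. Fully
#' reproducible given `cfg$seed`.
#'
#' @param truth a `potential_1d` ground truth.
#' @param window an `umbrella_window`, or NULL for an unbiased run.
#' @param cfg a `sim_config`.
#' @return a `time_series` (first 10\% of saved samples flagged burn-in by
#'   default).
#' @export
simulate_window <- function(truth, window = NULL, cfg) {
  if (!is.null(window)) stopifnot(inherits(window, "umbrella_window"))
  run_langevin(truth, cfg, window = window)
}

#' Simulate a regular set of umbrella windows
#'
#' One window per center on the grid `seq(z_first, z_last, by = spacing)`,
#' each started at its own center and simulated with the deterministic
#' per-window seed `cfg$seed + index - 1`, so window sets are reproducible yet
#' mutually independent streams. Warns when the adjacent-window histogram
#' overlap (fraction of a window's production samples falling into 0.5 A bins
#' also populated by its neighbour) drops below 5\%: WHAM cannot stitch
#' non-overlapping windows.
#'
#' @param truth a `potential_1d`.
#' @param z_first,z_last first and last window centers (Angstrom),
#'   z_first < z_last.
#' @param spacing window spacing in Angstrom (> 0).
#' @param spring spring constant k_s in kT/A^2, shared by all windows.
#' @param cfg a `sim_config`; `n_steps` and seed apply per window.
#' @return a list of `time_series`, one per window.
#' @export
generate_window_set <- function(truth, z_first, z_last, spacing, spring, cfg) {
  stopifnot(spacing > 0, z_first < z_last)
  centers <- seq(z_first, z_last, by = spacing)
  series <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    w <- umbrella_window(centers[i], spring)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    cfg_i$z_init <- cfg$z_init %||% centers[i]
    series[[i]] <- run_langevin(truth, cfg_i, window = w)
  }
  check_window_overlap(series)
  series
}

# adjacent-window shared-bin overlap diagnostic (0.5 A bins)
check_window_overlap <- function(series, bin = 0.5, warn_below = 0.05) {
  if (length(series) < 2) return(invisible(NULL))
  occ <- lapply(series, function(ts)
    unique(floor(production_samples(ts) / bin)))
  for (i in seq_len(length(series) - 1)) {
    zi <- floor(production_samples(series[[i]]) / bin)
    frac <- mean(zi %in% occ[[i + 1]])
    if (frac < warn_below)
      warning(sprintf(paste0("histogram overlap between windows %d and %d is ",
                             "%.1f%% (< 5%%); WHAM stitching may fail"),
                      i, i + 1, 100 * frac))
  }
  invisible(NULL)
}

#' Simulate a docking pull under a scheduled flat-bottom restraint
#'
#' Runs the Langevin generator with a time-dependent flat-bottom restraint
#' whose upper bound is reduced linearly from `b_start` to `b_end` over
#' `t_ramp` -- the protocol that slowly pulls a blocker into the pore -- and
#' held at `b_end` afterwards.
#'
#' @param truth a `potential_1d`.
#' @param restraint a `flat_bottom_restraint` with a schedule.
#' @param cfg a `sim_config` (`z_init` defaults to 0 if unset; set it near
#'   `b_start` to emulate a docking start).
#' @return a `time_series`.
#' @export
simulate_pull <- function(truth, restraint, cfg) {
  stopifnot(inherits(restraint, "flat_bottom_restraint"))
  if (is.null(restraint$schedule))
    stop("simulate_pull requires a restraint with a schedule")
  run_langevin(truth, cfg, restraint = restraint)
}
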