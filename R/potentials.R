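# Ground-truth / reconstructed free-energy curves and bias energy functions.
# All energies are carried in kT; lengths in Angstrom; spring constants in
# kT/A^2. Conversion to kcal/mol happens only at the I/O boundary.

#' One-dimensional free-energy potential
#'
#' Constructors for the `potential_1d` family used both as synthetic ground
#' truth for the Langevin simulator and as an analytic reference for
#' reconstructed profiles. Supported kinds:
#' \describe{
#'   \item{square well}{\eqn{W(z) = depth} for \eqn{|z - center| \le width/2},
#'     0 outside. `depth` is the energy *inside* the well, so a binding well
#'     has negative depth. The gradient is zero almost everywhere; simulating
#'     across the (discontinuous) walls is not supported.}
#'   \item{harmonic}{\eqn{W(z) = \frac{1}{2} k (z - center)^2}.}
#'   \item{double well}{a sum of Gaussian wells
#'     \eqn{W(z) = -\sum_i d_i \exp[-(z-c_i)^2 / (2 w_i^2)]}, the package's
#'     smooth stand-in for a binding profile: deep well at the bound state,
#'     optional secondary well, flat (W = 0) in the bulk.}
#'   \item{tabulated}{linear interpolation of a strictly increasing grid of
#'     (z, W) pairs; the grid ends define the domain.}
#' }
#'
#' @param depth well energy in kT (negative for a binding well); for
#'   `double_well_potential` a vector of well depths, here as positive
#'   magnitudes of the Gaussian wells.
#' @param width well width in Angstrom (full width for the square well,
#'   Gaussian sigma per well for the double well).
#' @param center well/minimum position in Angstrom; vector for the double well.
#' @param stiffness harmonic stiffness in kT/A^2.
#' @param z,W tabulated grid (Angstrom, kT), strictly increasing in `z`.
#' @param domain optional c(lo, hi) evaluation domain in Angstrom; defaults to
#'   unbounded for parametric kinds and to the grid span for tabulated ones.
#'   The Langevin simulator reflects trajectories at finite domain edges.
#' @return an object of class `potential_1d`.
#' @examples
#' p <- double_well_potential(depth = c(8, 3), center = c(10, 13),
#'                            width = c(1.5, 1.2))
#' evaluate_potential(p, 10)
#' @name potential_1d
NULL

new_potential <- function(kind, params, domain) {
  stopifnot(length(domain) == 2, domain[1] < domain[2])
  structure(list(kind = kind, params = params, domain = domain),
            class = "potential_1d")
}

#' @rdname potential_1d
#' @export
square_well_potential <- function(depth, width, center = 0,
                                  domain = c(-Inf, Inf)) {
  stopifnot(is.finite(depth), width > 0)
  new_potential("square_well",
                list(depth = depth, width = width, center = center), domain)
}

#' @rdname potential_1d
#' @export
harmonic_potential <- function(stiffness, center = 0, domain = c(-Inf, Inf)) {
  stopifnot(stiffness >= 0)
  new_potential("harmonic", list(stiffness = stiffness, center = center),
                domain)
}

#' @rdname potential_1d
#' @export
double_well_potential <- function(depth, center, width,
                                  domain = c(-Inf, Inf)) {
  stopifnot(length(depth) == length(center),
            length(center) == length(width),
            all(depth >= 0), all(width > 0))
  new_potential("double_well",
                list(depth = depth, center = center, width = width), domain)
}

#' @rdname potential_1d
#' @export
tabulated_potential <- function(z, W) {
  stopifnot(length(z) == length(W), length(z) >= 2,
            all(is.finite(z)), all(is.finite(W)), all(diff(z) > 0))
  new_potential("tabulated", list(z = as.numeric(z), W = as.numeric(W)),
                c(z[1], z[length(z)]))
}

#' @export
print.potential_1d <- function(x, ...) {
  cat("<potential_1d>", x$kind, "\n")
  if (x$kind == "tabulated") {
    cat("  grid:", length(x$params$z), "points on [",
        x$domain[1], ",", x$domain[2], "] A\n")
  } else {
    cat(" ", paste(names(x$params),
                   vapply(x$params, function(p) paste(signif(p, 4), collapse = ","),
                          ""), sep = "=", collapse = "  "), "\n")
    cat("  domain: [", x$domain[1], ",", x$domain[2], "] A\n")
  }
  invisible(x)
}

#' Evaluate a potential
#'
#' Returns \eqn{W(z)} in kT. Evaluation outside the domain is an error, never a
#' clamp: clamping would silently corrupt Boltzmann weights downstream.
#' Tabulated potentials interpolate linearly between grid points.
#'
#' @param p a `potential_1d`.
#' @param z positions in Angstrom (vectorised).
#' @return energies in kT.
#' @export
evaluate_potential <- function(p, z) {
  stopifnot(inherits(p, "potential_1d"), is.numeric(z))
  if (any(z < p$domain[1] | z > p$domain[2]))
    stop("position outside the potential domain [", p$domain[1], ", ",
         p$domain[2], "] A")
  par <- p$params
  switch(p$kind,
    square_well = ifelse(abs(z - par$center) <= par$width / 2, par$depth, 0),
    harmonic = 0.5 * par$stiffness * (z - par$center)^2,
    double_well = {
      W <- numeric(length(z))
      for (i in seq_along(par$depth))
        W <- W - par$depth[i] *
          exp(-0.5 * ((z - par$center[i]) / par$width[i])^2)
      W
    },
    tabulated = stats::approx(par$z, par$W, xout = z)$y
  )
}

#' Force of a potential
#'
#' \eqn{-dW/dz} in kT/A. Analytic for parametric kinds (zero almost everywhere
#' for the square well); tabulated potentials use central finite differences at
#' the grid nodes (one-sided at the ends), linearly interpolated between nodes.
#'
#' @inheritParams evaluate_potential
#' @return forces in kT/A.
#' @export
potential_force <- function(p, z) {
  stopifnot(inherits(p, "potential_1d"))
  par <- p$params
  switch(p$kind,
    square_well = numeric(length(z)),
    harmonic = -par$stiffness * (z - par$center),
    double_well = {
      f <- numeric(length(z))
      for (i in seq_along(par$depth)) {
        u <- (z - par$center[i]) / par$width[i]
        f <- f - par$depth[i] * u / par$width[i] * exp(-0.5 * u^2)
      }
      f
    },
    tabulated = {
      g <- tabulated_force_grid(p)
      stats::approx(g$z, g$F, xout = z)$y
    }
  )
}

# central-difference forces at tabulated grid nodes
tabulated_force_grid <- function(p) {
  z <- p$params$z; W <- p$params$W
  n <- length(z)
  F <- numeric(n)
  F[1] <- -(W[2] - W[1]) / (z[2] - z[1])
  F[n] <- -(W[n] - W[n - 1]) / (z[n] - z[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    F[i] <- -(W[i + 1] - W[i - 1]) / (z[i + 1] - z[i - 1])
  }
  list(z = z, F = F)
}

# largest curvature (kT/A^2) present in the potential; used by the simulator's
# timestep-stability check
potential_max_stiffness <- function(p) {
  par <- p$params
  switch(p$kind,
    square_well = 0,
    harmonic = par$stiffness,
    double_well = max(par$depth / par$width^2),
    tabulated = {
      W <- par$W; z <- par$z
      if (length(z) < 3) return(0)
      d2 <- abs(diff(diff(W) / diff(z)) / diff(z[-1]))
      max(c(0, d2[is.finite(d2)]))
    })
}

#' Example binding-well ground truth
#'
#' The package's canonical synthetic binding profile: a deep Gaussian well
#' (8 kT, the bound state) at z = 10 A with a shallow secondary well (3 kT) at
#' z = 13 A, flat (W = 0) in the bulk. This is the truth potential used by the
#' worked examples, the validation suite, and the acceptance pipeline.
#'
#' @return a `potential_1d` of the double-well kind.
#' @export
example_binding_potential <- function() {
  double_well_potential(depth = c(8, 3), center = c(10, 13),
                        width = c(1.5, 1.2))
}

#' Umbrella window
#'
#' One biased sampling window: a harmonic restraint of spring constant
#' `spring` (kT/A^2) centred at `center` (Angstrom). The bias convention is
#' \eqn{E = \frac{1}{2} k (z - z_0)^2} throughout the package; metadata files
#' declare their convention explicitly so the other dialect
#' (\eqn{E = k (z - z_0)^2}) is converted on load.
#'
#' @param center window center z0 in Angstrom.
#' @param spring spring constant in kT/A^2, > 0.
#' @param label optional window label.
#' @export
umbrella_window <- function(center, spring, label = NULL) {
  stopifnot(is.numeric(center), length(center) == 1,
            is.numeric(spring), length(spring) == 1, spring > 0)
  structure(list(center = center, spring = spring,
                 label = label %||% sprintf("z%.3g", center)),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> %s: center %.4g A, spring %.4g kT/A^2\n",
              x$label, x$center, x$spring))
  invisible(x)
}

#' Harmonic bias energy
#'
#' \eqn{\frac{1}{2} k_s (z - z_0)^2} in kT.
#'
#' @param w an `umbrella_window`.
#' @param z positions in Angstrom (vectorised).
#' @export
harmonic_bias_energy <- function(w, z) {
  stopifnot(inherits(w, "umbrella_window"))
  0.5 * w$spring * (z - w$center)^2
}

#' Flat-bottom distance restraint
#'
#' Zero inside the bound b, harmonic (\eqn{\frac{1}{2} k_{fb} (d-b)^2}) beyond
#' it. With a schedule, the bound is ramped linearly from `b_start` to `b_end`
#' over `t_ramp` and held constant afterwards -- the docking protocol that
#' pulls a blocker toward the pore without biasing the bound geometry.
#'
#' @param bound upper bound b in Angstrom (>= 0). Ignored when a schedule is
#'   given (the schedule defines b(t)).
#' @param stiffness restraint stiffness in kT/A^2 (> 0). The default 10 is a
#'   configurable placeholder typical of docking restraints.
#' @param schedule optional list(b_start, b_end, t_ramp) with b_start >= b_end
#'   and t_ramp > 0 (times in ps).
#' @export
flat_bottom_restraint <- function(bound = NULL, stiffness = 10,
                                  schedule = NULL) {
  stopifnot(stiffness > 0)
  if (!is.null(schedule)) {
    stopifnot(all(c("b_start", "b_end", "t_ramp") %in% names(schedule)),
              schedule$t_ramp > 0, schedule$b_end >= 0,
              schedule$b_start >= schedule$b_end)
    bound <- schedule$b_end
  }
  stopifnot(!is.null(bound), bound >= 0)
  structure(list(bound = bound, stiffness = stiffness, schedule = schedule),
            class = "flat_bottom_restraint")
}

#' Instantaneous flat-bottom bound b(t)
#'
#' @param r a `flat_bottom_restraint`.
#' @param t time in ps (vectorised); ignored without a schedule.
#' @export
flat_bottom_bound <- function(r, t = 0) {
  stopifnot(inherits(r, "flat_bottom_restraint"))
  if (is.null(r$schedule)) return(rep(r$bound, length(t)))
  s <- r$schedule
  frac <- pmin(pmax(t / s$t_ramp, 0), 1)
  s$b_start + (s$b_end - s$b_start) * frac
}

#' Flat-bottom restraint energy
#'
#' 0 for \eqn{d \le b(t)}, \eqn{\frac{1}{2} k_{fb} (d - b(t))^2} beyond; the
#' energy and its first derivative are continuous at d = b.
#'
#' @param r a `flat_bottom_restraint`.
#' @param d distance in Angstrom, >= 0 (vectorised).
#' @param t time in ps.
#' @export
flat_bottom_energy <- function(r, d, t = 0) {
  stopifnot(all(d >= 0))
  b <- flat_bottom_bound(r, t)
  ifelse(d <= b, 0, 0.5 * r$stiffness * (d - b)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
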