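# PMF -> dissociation constant for a blocker confined to a sampling cylinder,
# and the single-site fractional-block relation.

AVOGADRO <- 6.02214076e23 # 1/mol
KB_KCAL  <- 0.0019872041  # kcal/mol/K

#' Dissociation constant from a PMF profile
#'
#' Standard binding constant of a blocker whose center of mass was confined
#' to a cylinder of radius R during sampling:
#' \deqn{K_d^{-1} = 1000\,\pi R^2 N_A \int_{z_{min}}^{z_{max}}
#'       e^{-W(z)/kT}\, dz}
#' (SI lengths). Internally lengths stay in Angstrom and the prefactor
#' becomes \eqn{\pi R^2 I \times 10^{-27} N_A} with the integral I in
#' Angstrom -- algebraically identical (1 A^3 = 1e-27 L); a unit test asserts
#' the equivalence. The integral uses the trapezoidal rule over the profile's
#' bins inside [z_min, z_max]; unsampled (+Inf) bins are excluded with a
#' warning. z_min and z_max default to the profile's finite extremes: the
#' fully-bound edge and the bulk edge. The profile must be re-zeroed to the
#' bulk convention (W -> 0 in bulk) for the equation to hold.
#'
#' @param p a `pmf_profile`, bulk-zeroed, W in kT.
#' @param radius confinement cylinder radius R in Angstrom (default 8).
#' @param temperature temperature in K (recorded; W is already in kT).
#' @param z_min,z_max integration bounds in Angstrom. Equal bounds give I = 0
#'   and Kd = Inf (no binding); z_min > z_max is an error.
#' @return a `binding_result`: `kd` (mol/L), `kd_inv` (L/mol), `integral`
#'   (Angstrom), and the geometry that produced them.
#' @export
compute_kd <- function(p, radius = 8, temperature = 298.15,
                       z_min = NULL, z_max = NULL) {
  stopifnot(inherits(p, "pmf_profile"), radius > 0)
  fin <- which(is.finite(p$W))
  if (length(fin) == 0) stop("profile has no finite bins")
  z_min <- z_min %||% p$z[fin[1]]
  z_max <- z_max %||% p$z[fin[length(fin)]]
  if (z_min > z_max) stop("z_min must not exceed z_max")
  if (identical(p$convention, "min"))
    warning("profile is min-zeroed; Kd assumes the bulk convention (W -> 0 ",
            "in bulk)")
  sel <- p$z >= z_min & p$z <= z_max
  if (!any(sel)) stop("no profile bins inside [z_min, z_max]")
  z <- p$z[sel]; W <- p$W[sel]
  if (any(!is.finite(W))) {
    warning(sum(!is.finite(W)), " unsampled bin(s) inside the integration ",
            "range excluded")
    z <- z[is.finite(W)]; W <- W[is.finite(W)]
  }
  I <- if (length(z) >= 2) pracma::trapz(z, exp(-W)) else 0
  kd_inv <- pi * radius^2 * I * 1e-27 * AVOGADRO
  structure(list(kd = if (kd_inv > 0) 1 / kd_inv else Inf,
                 kd_inv = kd_inv, integral = I, radius = radius,
                 z_min = z_min, z_max = z_max, temperature = temperature),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat("<binding_result>\n")
  cat(sprintf("  cylinder radius: %.3g A; range: [%.4g, %.4g] A; T = %.2f K\n",
              x$radius, x$z_min, x$z_max, x$temperature))
  cat(sprintf("  integral exp(-W/kT) dz: %.6g A\n", x$integral))
  if (is.finite(x$kd)) {
    cat(sprintf("  Kd = %.3g M (%.3g uM); Ka = Kd^-1 = %.6g L/mol\n",
                x$kd, x$kd * 1e6, x$kd_inv))
  } else {
    cat("  Kd = Inf (no binding)\n")
  }
  invisible(x)
}

#' Conservative Kd interval from the profile uncertainty
#'
#' Recomputes Kd with the whole profile shifted by -sigma_max and +sigma_max:
#' a uniform shift factors out of the integral, so the bounds are exactly
#' Kd * exp(-sigma_max) and Kd * exp(+sigma_max). This is a conservative
#' bound matched to a single-number profile uncertainty (e.g. the bootstrap
#' sigma_max), not a standard error.
#'
#' @param p a `pmf_profile` (bulk-zeroed).
#' @param sigma_max profile uncertainty in kT (>= 0); defaults to the maximum
#'   of the profile's own pointwise `sigma` when present.
#' @inheritParams compute_kd
#' @return list with `kd_low`, `kd`, `kd_high` (mol/L), kd_low <= kd <= kd_high.
#' @export
kd_bounds <- function(p, sigma_max = NULL, radius = 8, temperature = 298.15,
                      z_min = NULL, z_max = NULL) {
  sigma_max <- sigma_max %||%
    if (!is.null(p$sigma)) max(p$sigma[is.finite(p$sigma)]) else
      stop("sigma_max not given and profile carries no uncertainty")
  stopifnot(sigma_max >= 0)
  mid <- compute_kd(p, radius, temperature, z_min, z_max)
  shift <- function(s) {
    q <- p; q$W <- q$W + s
    compute_kd(q, radius, temperature, z_min, z_max)$kd
  }
  list(kd_low = shift(-sigma_max), kd = mid$kd, kd_high = shift(sigma_max))
}

#' Single-site fractional block
#'
#' Fraction of current blocked at blocker concentration C for a one-site
#' blocker with dissociation constant Kd: C / (C + Kd). At C = Kd half the
#' current is blocked, which is how an IC50 maps onto Kd in this model.
#'
#' @param conc concentration in mol/L (>= 0, vectorised).
#' @param kd dissociation constant in mol/L (> 0).
#' @return blocked fraction in [0, 1].
#' @export
fraction_blocked <- function(conc, kd) {
  stopifnot(all(conc >= 0), kd > 0)
  conc / (conc + kd)
}
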