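#' Optical trap calibration
#'
#' Default stiffness and displacement conversion for the optical-tweezer
#' measurements: `kappa = 12.8` pN/um, `beta = 1/0.192` um/V, and thermal
#' energy `kBT` in pN.um (4.1e-3 at room temperature).
#'
#' @param kappa trap stiffness, pN/um.
#' @param beta voltage-to-displacement conversion, um/V.
#' @param kBT thermal energy, pN.um.
#' @return An object of class `trap_calibration`.
#' @export
trap_calibration <- function(kappa = 12.8, beta = 1 / 0.192, kBT = 4.1e-3) {
  if (kappa <= 0 || beta <= 0 || kBT <= 0)
    stop("calibration values must be positive")
  structure(list(kappa = kappa, beta = beta, kBT = kBT),
            class = "trap_calibration")
}

#' Linear trap force
#'
#' `F = kappa * (r - r0)`: the restoring force on a trapped particle
#' displaced from the trap center, applied componentwise for vector input.
#'
#' @param cal a [trap_calibration()].
#' @param r particle position(s), um.
#' @param r0 trap center, um.
#' @return Force in pN (same shape as `r`).
#' @examples
#' trap_force(trap_calibration(), 0.5, 0)  # 6.4 pN
#' @export
trap_force <- function(cal, r, r0 = 0) {
  stopifnot(inherits(cal, "trap_calibration"))
  cal$kappa * (r - r0)
}

#' Trap stiffness from Boltzmann position statistics
#'
#' The position distribution of a trapped particle in a harmonic trap is
#' Gaussian with log-density `-kappa * x^2 / (2 kBT) + const`.  A parabola is
#' fitted to the logarithm of the position histogram (Freedman-Diaconis
#' bins; empty bins masked; count-weighted, since the variance of a log
#' count scales inversely with the count) and the curvature converted to
#' stiffness.  A non-Gaussian flag is raised when the quadratic fit leaves
#' substantial residual structure or the log-histogram is not concave (in
#' which case no stiffness is returned).
#'
#' @param positions position samples, um (at least 100).
#' @param kBT thermal energy, pN.um.
#' @return List with `kappa` (pN/um), `kappa_gaussian` (kBT/var benchmark),
#'   `non_gaussian` flag, and `r_squared` of the log-parabola fit.
#' @export
trap_stiffness_boltzmann <- function(positions, kBT = 4.1e-3) {
  if (length(positions) < 100) stop("need at least 100 position samples")
  if (sd(positions) == 0) stop("fit error: degenerate (constant) positions")
  h <- graphics::hist(positions, breaks = "FD", plot = FALSE)
  keep <- h$counts > 0
  if (sum(keep) < 5) stop("fit error: too few occupied histogram bins")
  x <- h$mids[keep]
  ly <- log(h$counts[keep])
  # weights = counts: var(log N) ~ 1/N, so low-count tail bins do not drag
  # the curvature
  fit <- lm(ly ~ x + I(x^2), weights = h$counts[keep])
  c2 <- unname(coef(fit)[3])
  r2 <- summary(fit)$r.squared
  if (!is.finite(c2) || c2 >= 0)
    return(list(kappa = NA_real_, kappa_gaussian = kBT / var(positions),
                non_gaussian = TRUE, r_squared = r2))
  list(kappa = -2 * kBT * c2,
       kappa_gaussian = kBT / var(positions),
       non_gaussian = r2 < 0.95,
       r_squared = r2)
}

#' Stokeslet fluctuation profile inside the nucleus
#'
#' Mean-square nucleoplasmic flow velocity at radial fraction `u = r0 / R`
#' generated by a uniform density of independent fluctuating Stokeslet
#' sources on the nuclear membrane:
#' `<v^2>(u) = (v_nm^2 / u) * ln((1 + u) / (1 - u))`
#' (proportionality constant 1), with the analytic limit `2 * v_nm^2` at the
#' center.  Strictly increasing on (0, 1), log-divergent at the membrane.
#'
#' @param v_nm nuclear-membrane fluctuation velocity, um/s.
#' @param u radial fraction(s) in `[0, 1)`.
#' @param constant order-one proportionality constant (default 1).
#' @return Mean-square velocity, um^2/s^2.
#' @export
stokeslet_profile <- function(v_nm, u, constant = 1) {
  if (any(u < 0 | u >= 1)) stop("domain error: u must lie in [0, 1)")
  out <- ifelse(u == 0, 2 * v_nm^2,
                v_nm^2 / u * log((1 + u) / (1 - u)))
  constant * out
}

#' Nucleus volume average of the Stokeslet profile
#'
#' `3 * integral(u^2 * profile(u), 0, 1)`: the volume average of the
#' mean-square flow over the nucleus, finite despite the boundary
#' divergence.  Analytically equal to `3 * v_nm^2`, so the transduced flow
#' has the same order of magnitude as its membrane sources.
#'
#' @inheritParams stokeslet_profile
#' @param rel.tol quadrature tolerance.
#' @return Volume-averaged mean-square velocity, um^2/s^2.
#' @export
nucleus_average_v2 <- function(v_nm, constant = 1, rel.tol = 1e-10) {
  q <- integrate(function(u) 3 * u^2 * stokeslet_profile(1, u),
                 0, 1, rel.tol = rel.tol)
  if (q$abs.error > 1e-6) stop("numeric error: quadrature did not converge")
  constant * v_nm^2 * q$value
}

#' Peclet number
#'
#' `Pe = v * l / D`: the ratio of active transport (velocity scale times
#' fluctuation amplitude) to the observed diffusion.  `Pe > 1` indicates
#' activity-dominated dynamics.
#'
#' @param v active velocity scale, um/s.
#' @param l fluctuation amplitude scale, um.
#' @param D observed diffusion coefficient, um^2/s.
#' @return Dimensionless Peclet number.
#' @examples
#' peclet(0.3, 2.7, 0.16)  # ~5 at the droplet scale in the nucleoplasm
#' peclet(0.9, 0.5, 0.3)   # 1.5 inside droplets
#' @export
peclet <- function(v, l, D) {
  if (any(D <= 0)) stop("domain error: D must be positive")
  if (any(v < 0) || any(l < 0)) stop("domain error: v and l must be non-negative")
  v * l / D
}
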