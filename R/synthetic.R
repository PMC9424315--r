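# Seeded generators for every input class the analysis stages consume, with
# known ground truth so each fit has a parameter-recovery test that needs no
# external data.

# cache of Cholesky factors for fractional Gaussian increments, keyed by
# (n, alpha); covariance of fBm increments with per-axis MSD 2*D*t^alpha
.fgn_cache <- new.env(parent = emptyenv())

.fgn_chol <- function(n, alpha, dt) {
  key <- sprintf("%d_%.10g_%.10g", n, alpha, dt)
  if (!is.null(.fgn_cache[[key]])) return(.fgn_cache[[key]])
  k <- 0:(n - 1)
  acov <- dt^alpha * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha) / 2
  L <- chol(stats::toeplitz(acov) + diag(1e-12, n))
  .fgn_cache[[key]] <- L
  L
}

#' Generate a (sub)diffusive track
#'
#' Fractional-Gaussian-increment track whose ensemble MSD is
#' `2 * d * D * t^alpha` by construction (`alpha = 1` is ordinary Brownian
#' motion with uncorrelated increments; `alpha < 1` subdiffusion).
#'
#' @param n_steps number of increments (track has `n_steps + 1` samples).
#' @param dt sampling interval, s.
#' @param D generalized diffusion coefficient, um^2/s^alpha.
#' @param alpha anomalous exponent in (0, 2).
#' @param dim spatial dimension (2 or 3).
#' @param radius droplet radius attached to the track, um.
#' @param seed optional integer seed.
#' @return A [track()].
#' @export
gen_track <- function(n_steps = 100, dt = 0.5, D = 0.16, alpha = 1,
                      dim = 2, radius = 0.9, seed = NULL) {
  if (D <= 0) stop("domain error: D must be positive")
  if (alpha <= 0 || alpha >= 2) stop("domain error: alpha must be in (0, 2)")
  if (!is.null(seed)) set.seed(seed)
  if (abs(alpha - 1) < 1e-12) {
    inc <- matrix(rnorm(n_steps * dim, 0, sqrt(2 * D * dt)), n_steps, dim)
  } else {
    L <- .fgn_chol(n_steps, alpha, dt)
    inc <- sqrt(2 * D) * crossprod(L, matrix(rnorm(n_steps * dim), n_steps, dim))
  }
  pos <- apply(inc, 2, cumsum)
  pos <- rbind(0, pos)
  track(times = dt * (0:n_steps), positions = pos, radius = radius)
}

#' Generate a fluctuating droplet contour movie
#'
#' Circle of radius `base_radius` perturbed per angle by a sinusoid of
#' amplitude `a` with `periods` whole periods over the movie (so the exact
#' per-angle variance is `a^2 / 2`), plus optional Gaussian noise.
#'
#' @param frames number of frames (30 at 0.5 s in the standard protocol).
#' @param n_angles angular bins over `[0, 360)` degrees.
#' @param base_radius mean droplet radius, um (admission range is 2-2.7 um).
#' @param amplitude sinusoid amplitude `a`, um (must be < base_radius).
#' @param periods whole sinusoid periods across the movie.
#' @param noise_sd additive Gaussian noise on the radii, um.
#' @param seed optional integer seed.
#' @return A [contour_series()].
#' @export
gen_contour_movie <- function(frames = 30, n_angles = 360, base_radius = 2.4,
                              amplitude = 0.1, periods = 3, noise_sd = 0,
                              seed = NULL) {
  if (amplitude >= base_radius)
    stop("geometry error: amplitude must be smaller than the radius")
  if (!is.null(seed)) set.seed(seed)
  phase <- runif(n_angles, 0, 2 * pi)
  tt <- (seq_len(frames) - 1) / frames * 2 * pi * periods
  r <- outer(tt, phase, function(w, p) base_radius + amplitude * sin(w + p))
  if (noise_sd > 0) r <- r + rnorm(length(r), 0, noise_sd)
  contour_series(r)
}

#' Generate a one-phase FRAP recovery curve
#'
#' Raw intensities following `background + (prebleach - background) *
#' plateau * (1 - exp(-t / tau))` plus multiplicative Gaussian noise; the
#' plateau below 1 is the mobile fraction ground truth.
#'
#' @param times time from bleach, s.
#' @param tau recovery timescale, s.
#' @param plateau recovery plateau as a fraction of prebleach (mobile
#'   fraction ground truth).
#' @param prebleach,background raw intensity levels.
#' @param noise_sd relative Gaussian noise (fraction of the prebleach span).
#' @param droplet_radius droplet radius, um.
#' @param seed optional integer seed.
#' @return List with `times`, `raw`, `prebleach`, `background`,
#'   `droplet_radius` and the ground-truth parameters, ready for
#'   [normalize_recovery()].
#' @export
gen_frap_curve <- function(times = seq(0, 120, by = 1), tau = 10,
                           plateau = 0.8, prebleach = 1000, background = 100,
                           noise_sd = 0, droplet_radius = 2, seed = NULL) {
  if (tau <= 0 || plateau <= 0) stop("domain error: tau and plateau must be positive")
  if (!is.null(seed)) set.seed(seed)
  span <- prebleach - background
  clean <- plateau * (1 - exp(-times / tau))
  raw <- background + span * clean
  if (noise_sd > 0) raw <- raw + rnorm(length(raw), 0, noise_sd * span)
  list(times = times, raw = raw, prebleach = prebleach,
       background = background, droplet_radius = droplet_radius,
       truth = list(tau = tau, plateau = plateau))
}

#' Generate trapped-particle positions
#'
#' Boltzmann-distributed positions in a harmonic trap: Gaussian with
#' variance `kBT / kappa`.
#'
#' @param n sample count.
#' @param kappa trap stiffness, pN/um.
#' @param kBT thermal energy, pN.um.
#' @param seed optional integer seed.
#' @return Numeric vector of positions, um.
#' @export
gen_trap_positions <- function(n = 1e5, kappa = 12.8, kBT = 4.1e-3,
                               seed = NULL) {
  if (kappa <= 0 || kBT <= 0) stop("domain error: kappa and kBT must be positive")
  if (!is.null(seed)) set.seed(seed)
  rnorm(n, 0, sqrt(kBT / kappa))
}

#' Generate a decorrelating pixel stack
#'
#' Each frame keeps a pixel with probability `1 - p` and resamples it from
#' the stationary intensity distribution with probability `p`, so the
#' consecutive-frame Pearson correlation is `1 - p` in expectation and the
#' stirring intensity recovers `p`.
#'
#' @param frames,height,width stack dimensions.
#' @param p per-frame pixel resampling fraction in `[0, 1]`.
#' @param seed optional integer seed.
#' @return 3-D array `[frame, row, col]`.
#' @export
gen_pixel_stack <- function(frames = 20, height = 64, width = 64, p = 0.5,
                            seed = NULL) {
  if (p < 0 || p > 1) stop("domain error: p must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  npix <- height * width
  stack <- array(0, c(frames, height, width))
  cur <- rnorm(npix)
  stack[1, , ] <- cur
  for (tt in seq_len(frames - 1)) {
    flip <- runif(npix) < p
    cur[flip] <- rnorm(sum(flip))
    stack[tt + 1, , ] <- cur
  }
  stack
}
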