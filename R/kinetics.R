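#' Particle track container
#'
#' @param times sample times, s (uniform spacing).
#' @param positions matrix of positions, um; 2 or 3 columns.
#' @param radius particle radius, um.
#' @param drift_reference optional companion position matrix (same shape) used
#'   for drift correction, e.g. the nucleus centroid trajectory.
#' @return An object of class `track`.
#' @export
track <- function(times, positions, radius = NA_real_, drift_reference = NULL) {
  positions <- as.matrix(positions)
  if (length(times) != nrow(positions)) stop("times/positions length mismatch")
  if (length(times) >= 3) {
    dts <- diff(times)
    if (max(abs(dts - dts[1])) > 1e-6 * max(abs(dts)))
      stop("track sampling must be uniform")
  }
  if (!is.null(drift_reference)) {
    drift_reference <- as.matrix(drift_reference)
    stopifnot(all(dim(drift_reference) == dim(positions)))
  }
  structure(list(times = as.numeric(times), positions = positions,
                 radius = radius, drift_reference = drift_reference),
            class = "track")
}

#' Time-averaged mean squared displacement
#'
#' For each lag `k * dt` up to `max_lag`, averages the squared displacement
#' over all start points (overlapping windows).  When a drift reference is
#' attached to the track it is subtracted first.
#'
#' @param tr a [track()].
#' @param max_lag largest lag in seconds (default: half the track span).
#' @return An object of class `msd_fit` with `lags` (s) and `msd` (um^2),
#'   spatial dimension `dim`, and the track radius.
#' @export
temporal_msd <- function(tr, max_lag = NULL) {
  stopifnot(inherits(tr, "track"))
  p <- tr$positions
  if (nrow(p) < 2) stop("input error: need at least 2 samples")
  if (!is.null(tr$drift_reference)) p <- p - tr$drift_reference
  dt <- tr$times[2] - tr$times[1]
  span <- tr$times[length(tr$times)] - tr$times[1]
  if (is.null(max_lag)) max_lag <- span / 2
  kmax <- min(nrow(p) - 1, max(1, floor(max_lag / dt + 1e-9)))
  msd <- vapply(seq_len(kmax), function(k) {
    d <- p[-seq_len(k), , drop = FALSE] - p[seq_len(nrow(p) - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  structure(list(lags = dt * seq_len(kmax), msd = msd, dim = ncol(p),
                 radius = tr$radius),
            class = "msd_fit")
}

#' Fit the anomalous diffusion exponent
#'
#' Least-squares fit of `msd = C * lag^alpha` by Nelder-Mead minimisation,
#' initialised from a log-log regression.  `alpha = 1` is free diffusion;
#' `alpha < 1` subdiffusion; `alpha = 2` ballistic motion.
#'
#' @param fit an `msd_fit` from [temporal_msd()].
#' @return The fit with `alpha`, `C` and `residual` (RSS) filled in.
#' @export
fit_alpha <- function(fit) {
  stopifnot(inherits(fit, "msd_fit"))
  ok <- fit$lags > 0 & fit$msd > 0
  if (!all(is.finite(fit$msd))) stop("input error: non-finite MSD values")
  if (sum(ok) < 5) stop("input error: need at least 5 positive-lag MSD points")
  lag <- fit$lags[ok]; msd <- fit$msd[ok]
  init <- coef(lm(log(msd) ~ log(lag)))
  obj <- function(p) sum((msd - exp(p[1]) * lag^p[2])^2)
  opt <- optim(c(init[1], init[2]), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  fit$alpha <- unname(opt$par[2])
  fit$C <- unname(exp(opt$par[1]))
  fit$residual <- opt$value
  fit
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD over %d lags (dim %d)", length(x$lags), x$dim))
  if (!is.null(x$alpha)) cat(sprintf("; alpha = %.3f", x$alpha))
  if (!is.null(x$D_eff)) cat(sprintf("; D_eff = %.4g um^2/s", x$D_eff))
  cat("\n")
  invisible(x)
}

#' Effective diffusion coefficient from the short-time MSD
#'
#' Unconstrained linear fit of the first `n_points` MSD points;
#' `D_eff = slope / (2 * d)` with `d` the spatial dimension, and
#' `D_eff_normalized = D_eff * (3/2) * pi * r` (um^3/s), the droplet-size
#' normalisation used to compare droplets of different radii.
#'
#' @param fit an `msd_fit`.
#' @param radius droplet radius, um (defaults to the track radius).
#' @param n_points number of leading MSD points in the linear fit (40 points
#'   at 0.5 s sampling = the standard 20 s window).
#' @return The fit with `D_eff` and `D_eff_normalized` filled in.
#' @export
effective_diffusion <- function(fit, radius = fit$radius, n_points = 40) {
  stopifnot(inherits(fit, "msd_fit"))
  if (length(fit$lags) < n_points)
    stop("window error: MSD has fewer than ", n_points, " points")
  lag <- fit$lags[seq_len(n_points)]
  msd <- fit$msd[seq_len(n_points)]
  slope <- unname(coef(lm(msd ~ lag))[2])
  fit$D_eff <- slope / (2 * fit$dim)
  fit$D_eff_normalized <- if (is.na(radius)) NA_real_ else
    fit$D_eff * (3 / 2) * pi * radius
  fit
}

#' Droplet number and size evolution from a coalescence log
#'
#' Reconstructs the droplet population over the event log: the droplet count
#' as a percentage of the initial count, and the mean maximal cross-section
#' surface `pi * r^2`.
#'
#' @param events event log data frame (`time`, `id_a`, `id_b`, `merged_id`,
#'   `merged_radius`).
#' @param initial_droplets data frame with columns `id` and `radius` for the
#'   initial droplet population.
#' @return Data frame with `time`, `n_droplets`, `pct_initial`,
#'   `mean_surface_um2`; the first row is the initial state (100%).
#' @export
count_and_size_curves <- function(events, initial_droplets) {
  stopifnot(all(c("id", "radius") %in% names(initial_droplets)))
  radii <- setNames(initial_droplets$radius, as.character(initial_droplets$id))
  n0 <- length(radii)
  out <- data.frame(time = 0, n_droplets = n0, pct_initial = 100,
                    mean_surface_um2 = mean(pi * radii^2))
  if (nrow(events) == 0) return(out)
  events <- events[order(events$time), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    radii <- radii[!names(radii) %in% as.character(c(ev$id_a, ev$id_b))]
    radii[as.character(ev$merged_id)] <- ev$merged_radius
    out <- rbind(out, data.frame(
      time = ev$time, n_droplets = length(radii),
      pct_initial = 100 * length(radii) / n0,
      mean_surface_um2 = mean(pi * radii^2)))
  }
  rownames(out) <- NULL
  out
}
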