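#' Radial contour profile
#'
#' Distance from a center to the boundary of a closed contour along rays at
#' fixed angular increments (1 degree by default).  The contour can be a
#' polygon (2-column vertex matrix, um) or a binary mask (logical/0-1 matrix
#' indexed mask[ix, iy] on a pixel grid) with a pixel pitch; for masks the
#' boundary is located by linear interpolation along the ray (sub-pixel),
#' taking the first crossing from the center.
#'
#' @param boundary polygon vertex matrix (closed implicitly) or binary mask
#'   matrix.
#' @param center 2-vector; um for polygons, pixel coordinates for masks.
#' @param n_angles number of angular bins covering `[0, 360)` degrees.
#' @param pixel_pitch um per pixel (masks only).
#' @return Numeric vector of radii (um), one per angle starting at 0 degrees.
#' @export
radial_profile <- function(boundary, center, n_angles = 360, pixel_pitch = 1) {
  theta <- (seq_len(n_angles) - 1) / n_angles * 2 * pi
  if (is.logical(boundary) || all(boundary %in% c(0, 1))) {
    m <- (boundary > 0) * 1
    if (m[round(center[1]), round(center[2])] == 0)
      stop("geometry error: center outside the contour")
    rmaxpix <- sqrt(nrow(m)^2 + ncol(m)^2)
    interp <- function(px, py) {
      # bilinear interpolation of the mask, 0 outside
      x0 <- floor(px); y0 <- floor(py)
      if (x0 < 1 || y0 < 1 || x0 + 1 > nrow(m) || y0 + 1 > ncol(m)) return(0)
      fx <- px - x0; fy <- py - y0
      m[x0, y0] * (1 - fx) * (1 - fy) + m[x0 + 1, y0] * fx * (1 - fy) +
        m[x0, y0 + 1] * (1 - fx) * fy + m[x0 + 1, y0 + 1] * fx * fy
    }
    out <- vapply(theta, function(a) {
      dirx <- cos(a); diry <- sin(a)
      step <- 0.25
      prev_t <- 0; prev_v <- 1
      t <- step
      while (t < rmaxpix) {
        v <- interp(center[1] + t * dirx, center[2] + t * diry)
        if (v < 0.5) {
          # linear interpolation of the 0.5 crossing between prev_t and t
          frac <- if (prev_v > v) (prev_v - 0.5) / (prev_v - v) else 0
          return((prev_t + frac * (t - prev_t)) * pixel_pitch)
        }
        prev_t <- t; prev_v <- v
        t <- t + step
      }
      NA_real_
    }, numeric(1))
    return(out)
  }

  poly <- as.matrix(boundary)
  n <- nrow(poly)
  if (n < 3) stop("geometry error: polygon needs at least 3 vertices")
  px <- poly[, 1] - center[1]
  py <- poly[, 2] - center[2]
  nxt <- c(2:n, 1)
  out <- vapply(theta, function(a) {
    dx <- cos(a); dy <- sin(a)
    best <- Inf
    for (i in seq_len(n)) {
      x1 <- px[i]; y1 <- py[i]; x2 <- px[nxt[i]]; y2 <- py[nxt[i]]
      ex <- x2 - x1; ey <- y2 - y1
      den <- dx * ey - dy * ex
      if (abs(den) < 1e-14) next
      # ray: t*(dx,dy); edge: (x1,y1) + u*(ex,ey)
      t <- (x1 * ey - y1 * ex) / den
      u <- (x1 * dy - y1 * dx) / den
      if (t > 1e-12 && u >= -1e-12 && u <= 1 + 1e-12) best <- min(best, t)
    }
    if (!is.finite(best)) stop("geometry error: center outside the contour")
    best
  }, numeric(1))
  out
}

#' Contour time series
#'
#' @param radii matrix of radii, um: frames in rows, angles in columns.
#' @param angles_deg angle grid in degrees (defaults to 1-degree bins).
#' @return An object of class `contour_series`.
#' @export
contour_series <- function(radii, angles_deg = NULL) {
  radii <- as.matrix(radii)
  if (is.null(angles_deg))
    angles_deg <- (seq_len(ncol(radii)) - 1) / ncol(radii) * 360
  if (any(radii <= 0, na.rm = TRUE)) stop("radii must be positive")
  structure(list(radii = radii, angles_deg = angles_deg),
            class = "contour_series")
}

#' Droplet surface fluctuation variance
#'
#' For each angle, the temporal mean radius `R(theta)` is subtracted and the
#' mean of `(r - R)^2` over frames is returned (population variance); the
#' scalar summary is its mean over angles.  Angles with missing radii are
#' masked from the summary and flagged.
#'
#' @param series a [contour_series()].
#' @return List with `per_angle` (um^2 per angle), `mean` (scalar summary,
#'   um^2), and `masked_angles` (indices excluded for missing data).
#' @export
fluctuation_variance <- function(series) {
  stopifnot(inherits(series, "contour_series"))
  r <- series$radii
  if (nrow(r) < 2) stop("need at least 2 frames")
  per_angle <- apply(r, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) return(NA_real_)
    mean((col - mean(col))^2)
  })
  masked <- which(!is.finite(per_angle) | colSums(!is.finite(r)) > 0)
  if (length(masked))
    warning("angles with missing radii masked from the summary: ",
            length(masked))
  list(per_angle = per_angle, mean = mean(per_angle, na.rm = TRUE),
       masked_angles = masked)
}

#' Radius-range admission filter
#'
#' Standard droplet admission for surface-fluctuation analyses: only droplets
#' whose mean radius lies in `[2, 2.7]` um are analysed.
#'
#' @param series a [contour_series()].
#' @param range admitted radius range, um.
#' @return `TRUE` if the droplet passes the filter.
#' @export
admit_radius_range <- function(series, range = c(2, 2.7)) {
  stopifnot(inherits(series, "contour_series"))
  m <- mean(series$radii, na.rm = TRUE)
  m >= range[1] && m <= range[2]
}
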