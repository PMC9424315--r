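#' Frame-to-frame image correlation
#'
#' Pearson correlation of pixel intensities per region, either between each
#' frame and the preceding one (`mode = "consecutive"`) or between each frame
#' and the first (`mode = "first"`).  Correlations from multiple regions are
#' averaged.  Constant (zero-variance) regions are masked with a warning.
#'
#' @param stack 3-D array `[frame, row, col]` of intensities (>= 2 frames).
#' @param regions list of regions, each `list(rows = i1:i2, cols = j1:j2)`;
#'   `NULL` uses the whole frame as one region.
#' @param mode reference frame convention; both are standard readouts.
#' @return Data frame with `frame`, `correlation` (region-averaged).
#' @export
frame_correlation <- function(stack, regions = NULL,
                              mode = c("consecutive", "first")) {
  mode <- match.arg(mode)
  d <- dim(stack)
  if (length(d) != 3 || d[1] < 2) stop("stack must be [frames, rows, cols] with >= 2 frames")
  if (is.null(regions)) regions <- list(list(rows = seq_len(d[2]), cols = seq_len(d[3])))
  for (rg in regions)
    if (max(rg$rows) > d[2] || max(rg$cols) > d[3] || min(rg$rows) < 1 || min(rg$cols) < 1)
      stop("region out of bounds")
  nT <- d[1]
  vals <- matrix(NA_real_, nT - 1, length(regions))
  masked <- FALSE
  for (g in seq_along(regions)) {
    rg <- regions[[g]]
    for (tt in 2:nT) {
      ref <- if (mode == "consecutive") tt - 1 else 1
      a <- as.vector(stack[ref, rg$rows, rg$cols])
      b <- as.vector(stack[tt, rg$rows, rg$cols])
      if (sd(a) == 0 || sd(b) == 0) { masked <- TRUE; next }
      vals[tt - 1, g] <- cor(a, b)
    }
  }
  if (masked) warning("constant (zero-variance) regions masked")
  data.frame(frame = 2:nT, correlation = rowMeans(vals, na.rm = TRUE))
}

#' Cytoplasmic stirring intensity
#'
#' Inverts the frame correlations (`1 - correlation`) so that a static image
#' gives 0 and fully decorrelated frames give 1; the scalar summary is the
#' mean over timepoints.
#'
#' @param correlations data frame from [frame_correlation()] or a numeric
#'   vector of correlations in `[-1, 1]`.
#' @return List with `intensity` (per timepoint) and `mean` (scalar).
#' @export
stirring_intensity <- function(correlations) {
  v <- if (is.data.frame(correlations)) correlations$correlation else correlations
  if (any(v < -1 - 1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  inv <- 1 - v
  list(intensity = inv, mean = mean(inv, na.rm = TRUE))
}
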