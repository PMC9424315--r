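#' Normalise a FRAP recovery curve
#'
#' Background-corrects the raw droplet intensity and normalises by the
#' prebleach level: `(raw - background) / (prebleach - background)`.  Time
#' zero is the bleach; the curve is shifted so the bleach value is zero.  The
#' 0-to-1 rescaling against full recovery uses the fitted plateau (see
#' [fit_one_phase()]), which is robust to noise in the last samples.
#'
#' @param times time from bleach, s.
#' @param raw_intensity raw droplet fluorescence.
#' @param prebleach,background prebleach and background intensity levels.
#' @param droplet_radius droplet radius, um (for [apparent_diffusion()]).
#' @return An object of class `recovery_curve` with `times` and `intensity`
#'   (prebleach-normalised, 0 at bleach).
#' @export
normalize_recovery <- function(times, raw_intensity, prebleach, background = 0,
                               droplet_radius = NA_real_) {
  if (prebleach <= background)
    stop("normalization error: prebleach must exceed background")
  norm <- (raw_intensity - background) / (prebleach - background)
  norm <- norm - norm[1]  # bleach value defines zero
  structure(list(times = as.numeric(times), intensity = norm,
                 droplet_radius = droplet_radius),
            class = "recovery_curve")
}

#' One-phase association fit
#'
#' Least-squares fit of `I(t) = A * (1 - exp(-t / tau))` to the normalised
#' recovery.  Initialisation: `A` is the mean of the last quartile of the
#' curve and `tau` the time to reach `A * (1 - 1/e)`.  The fitted plateau `A`
#' is the full-recovery reference for the 0-to-1 rescaling.
#'
#' @param curve a [normalize_recovery()] result (or a list with `times` and
#'   `intensity`).
#' @return List with `tau` (s), `amplitude`, `rescaled` (curve divided by the
#'   plateau) and the `nls`-style fitted object.
#' @export
fit_one_phase <- function(curve) {
  t <- curve$times
  y <- curve$intensity
  if (length(t) < 10) stop("input error: need at least 10 post-bleach points")
  A0 <- mean(y[t >= stats::quantile(t, 0.75)])
  if (!is.finite(A0) || A0 <= 0)
    stop("fit error: no recovery detected (flat or non-positive curve)")
  thr <- A0 * (1 - exp(-1))
  i <- which(y >= thr)
  tau0 <- if (length(i)) max(t[i[1]], t[2]) else max(t) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-t / tau)),
                      start = list(A = A0, tau = tau0),
                      lower = c(1e-9, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit error: one-phase fit failed (", conditionMessage(e), ")"))
  cf <- coef(fit)
  list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
       rescaled = y / unname(cf["A"]), fit = fit)
}

#' Apparent diffusion coefficient from FRAP
#'
#' `D_app = r^2 / tau` (proportionality constant taken as 1; values are
#' comparable among themselves but carry that arbitrary constant when
#' compared with other diffusion estimates).
#'
#' @param radius droplet radius, um.
#' @param tau one-phase recovery timescale, s.
#' @param constant proportionality constant (default 1).
#' @return D_app in um^2/s.
#' @examples
#' apparent_diffusion(2, 10)  # 0.4
#' @export
apparent_diffusion <- function(radius, tau, constant = 1) {
  if (any(radius <= 0) || any(tau <= 0))
    stop("domain error: radius and tau must be positive")
  constant * radius^2 / tau
}

#' Mobile fraction at the stage-specific window
#'
#' The normalised intensity recovered at 120 s for NSN oocytes and at 60 s
#' for SN oocytes (the plateau times of control recovery curves).  Linear
#' interpolation between samples.
#'
#' @param curve a `recovery_curve`.
#' @param stage `"NSN"` (120 s) or `"SN"` (60 s).
#' @return Recovered fraction at the window.
#' @export
mobile_fraction <- function(curve, stage = c("NSN", "SN")) {
  stage <- match.arg(stage)
  w <- if (stage == "NSN") 120 else 60
  if (max(curve$times) < w)
    stop("window error: curve does not span the ", w, " s window")
  stats::approx(curve$times, curve$intensity, xout = w)$y
}
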