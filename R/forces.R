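#' Activity-dependent diffusion law
#'
#' The diffusion coefficient of an agent combines a passive component `D0`
#' with an active component proportional to the cytoplasmic stirring activity
#' `A`: the base coefficient is `D0 + alpha_act * A`, calibrated for an agent
#' of `reference_radius` with unit friction.  Individual agents scale it by
#' Stokes' law (`reference_radius / r`) and their dimensionless friction
#' multiplier.
#'
#' @param D0 minimal mobility in um^2/s at zero activity (default 0.01).
#' @param alpha_act coefficient of mobility per activity unit (default 0.11).
#' @param activity dimensionless cytoplasmic stirring activity `A` (>= 0).
#' @param reference_radius radius in um at which `D0` and `alpha_act` were
#'   calibrated (the nucleolus, 4.5 um).
#' @return An object of class `diffusion_law`.
#' @seealso [agent_diffusion()]
#' @export
diffusion_law <- function(D0 = 0.01, alpha_act = 0.11, activity = 0.55,
                          reference_radius = 4.5) {
  if (D0 < 0 || alpha_act < 0) stop("D0 and alpha_act must be non-negative")
  if (activity < 0) stop("activity must be non-negative")
  if (reference_radius <= 0) stop("reference_radius must be positive")
  structure(list(D0 = D0, alpha_act = alpha_act, activity = activity,
                 reference_radius = reference_radius),
            class = "diffusion_law")
}

#' @export
print.diffusion_law <- function(x, ...) {
  cat(sprintf("Diffusion law: D = (%.4g + %.4g * A) * (r_ref/r) / f, A = %.4g, r_ref = %.3g um\n",
              x$D0, x$alpha_act, x$activity, x$reference_radius))
  invisible(x)
}

#' Force field strengths
#'
#' Linear overlap penalties: a repulsion of magnitude `k * overlap` acts along
#' the center line as soon as two spheres (or a sphere and the nuclear
#' membrane) overlap.  Droplet-involving contacts use the soft strength,
#' obstacle/nucleolus contacts the hard strength.  Forces are expressed in
#' units of `gamma * um^2/s` so that `gamma = 1` sets the friction scale.
#'
#' @param k_confine nucleus-membrane repulsion strength (default 30).
#' @param k_hard obstacle/nucleolus pair repulsion strength (default 30).
#' @param k_soft droplet-involving pair repulsion strength (default 10).
#' @param gamma nucleoplasm viscosity scale (default 1).
#' @return An object of class `force_field`.
#' @export
force_field <- function(k_confine = 30, k_hard = 30, k_soft = 10, gamma = 1) {
  if (any(c(k_confine, k_hard, k_soft) < 0)) stop("force strengths must be >= 0")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(k_confine = k_confine, k_hard = k_hard, k_soft = k_soft,
                 gamma = gamma), class = "force_field")
}

#' Diffusion coefficient of an agent
#'
#' `D_i = (D0 + alpha_act * A) * (reference_radius / r_i) / f_i`: strictly
#' decreasing in radius (Stokes scaling) and in the friction multiplier,
#' strictly increasing in activity.
#'
#' @param law a [diffusion_law()].
#' @param radius agent radius in um (vectorised).
#' @param friction dimensionless friction multiplier (vectorised).
#' @return Diffusion coefficient(s) in um^2/s.
#' @examples
#' law <- diffusion_law(activity = 0)
#' agent_diffusion(law, radius = 4.5, friction = 1)  # 0.01
#' @export
agent_diffusion <- function(law, radius, friction = 1) {
  stopifnot(inherits(law, "diffusion_law"))
  if (any(radius <= 0)) stop("invalid agent: radius must be positive")
  if (any(friction <= 0)) stop("invalid agent: friction must be positive")
  (law$D0 + law$alpha_act * law$activity) * (law$reference_radius / radius) / friction
}

# dimensionless friction eta_i = (r_i / r_ref) * f_i opposing deterministic drift
.agent_eta <- function(law, radius, friction) {
  (radius / law$reference_radius) * friction
}

#' Confinement force at the nuclear membrane
#'
#' Zero while the agent is fully inside the nucleus; once the agent surface
#' crosses the membrane (`|position| + r > R`) an inward force of magnitude
#' `k_confine * (|position| + r - R)` acts toward the nucleus center.
#' Continuous at contact.
#'
#' @param position 3-vector, um, nucleus-centered.
#' @param radius agent radius, um.
#' @param R nucleus radius, um.
#' @param field a [force_field()].
#' @return 3-vector force.
#' @export
confinement_force <- function(position, radius, R, field = force_field()) {
  if (R <= 0) stop("config error: nucleus radius must be positive")
  if (radius <= 0) stop("invalid agent: radius must be positive")
  d <- sqrt(sum(position^2))
  over <- d + radius - R
  if (over <= 0 || d < 1e-12) return(c(0, 0, 0))
  -field$k_confine * over * position / d
}

#' Pairwise overlap repulsion
#'
#' Equal and opposite forces of magnitude `k * overlap` along the center line
#' when two spheres overlap; `k` is the soft strength when a droplet is
#' involved and the hard strength otherwise.  Coincident centers are resolved
#' along a deterministic coordinate axis derived from the lower agent id.
#'
#' @param a,b lists with elements `position` (3-vector), `radius`, `kind`
#'   (one of `"droplet"`, `"nucleolus"`, `"obstacle"`), and optionally `id`.
#' @param field a [force_field()].
#' @return List with `force_a` and `force_b` (3-vectors), summing to zero.
#' @export
pair_repulsion <- function(a, b, field = force_field()) {
  if (a$radius <= 0 || b$radius <= 0) stop("invalid agent: radius must be positive")
  dvec <- a$position - b$position
  d <- sqrt(sum(dvec^2))
  s <- a$radius + b$radius
  if (d >= s) return(list(force_a = c(0, 0, 0), force_b = c(0, 0, 0)))
  if (d < 1e-12) {
    ida <- if (is.null(a$id)) 0L else a$id
    idb <- if (is.null(b$id)) 1L else b$id
    lo <- min(ida, idb)
    nrm <- c(0, 0, 0)
    nrm[lo %% 3 + 1] <- 1
    if (ida > idb) nrm <- -nrm
  } else {
    nrm <- dvec / d
  }
  k <- if (identical(a$kind, "droplet") || identical(b$kind, "droplet"))
    field$k_soft else field$k_hard
  fmag <- k * (s - d)
  list(force_a = fmag * nrm, force_b = -fmag * nrm)
}

#' Coalesce two droplets
#'
#' The pair is replaced by a single sphere whose volume is the sum of the two
#' original volumes (`r = (r_a^3 + r_b^3)^(1/3)`), positioned at the
#' volume-weighted centroid of the two centers.
#'
#' @param a,b lists with `position`, `radius` and `kind = "droplet"`.
#' @return List with `position`, `radius`, `kind`.
#' @export
coalesce <- function(a, b) {
  if (!identical(a$kind, "droplet") || !identical(b$kind, "droplet"))
    stop("kind error: only droplets coalesce")
  va <- a$radius^3
  vb <- b$radius^3
  v <- va + vb
  pos <- if (v > 0) (va * a$position + vb * b$position) / v else a$position
  list(position = pos, radius = v^(1/3), kind = "droplet")
}
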