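#' Simulation configuration
#'
#' Defaults reproduce the standard nucleus: radius 12 um; one nucleolus
#' (4.5 +/- 0.2 um, friction 1); 55 droplets (0.9 +/- 0.01 um, friction 0.55);
#' 875 chromatin-like obstacles (0.85 +/- 0.4 um truncated at 0.05 um,
#' friction 5); nucleus repulsion 30, hard repulsion 30, droplet repulsion 10;
#' time step 0.01 s; NSN-to-SN transition at 12 h with 40% obstacle anchoring
#' and a 1.8-fold activity increase.
#'
#' `obstacle_scale` < 1 enables the scaled-down mode: the obstacle count is
#' multiplied by the scale and radii are rescaled by `scale^(-1/3)` so the
#' total obstacle volume fraction is preserved; scaled runs are flagged in
#' summary metadata.
#'
#' @param nucleus_radius nucleus radius, um.
#' @param nucleolus_radius,nucleolus_radius_sd mean and Gaussian spread of the
#'   nucleolus radius, um.
#' @param nucleolus_friction friction multiplier of the nucleolus.
#' @param n_droplets,droplet_radius,droplet_radius_sd,droplet_friction droplet
#'   count, radius distribution (um) and friction multiplier.
#' @param n_obstacles,obstacle_radius,obstacle_radius_sd,obstacle_radius_min,obstacle_friction
#'   obstacle count, truncated-Gaussian radius distribution (um) and friction.
#' @param k_confine,k_hard,k_soft,gamma see [force_field()].
#' @param D0,alpha_act see [diffusion_law()].
#' @param reference_radius calibration radius of the diffusion law, um.
#' @param dt integration time step, s.
#' @param sample_dt summary sampling cadence, s (default 300 s = 5 min).
#' @param transition_time_h,anchored_fraction,activity_multiplier NSN-to-SN
#'   transition time (h), fraction of obstacles anchored, and activity
#'   multiplier applied at the transition.
#' @param tether_theta,tether_sigma,tether_cap Ornstein-Uhlenbeck tether of
#'   anchored obstacles: relaxation rate (1/s), noise amplitude (um/sqrt(s)),
#'   and displacement cap (um).
#' @param drift_cap maximum deterministic drift per agent per step, um (only
#'   binds while strong transient overlaps relax).
#' @param obstacle_scale scaled-down mode factor in (0, 1]; 1 = full fidelity.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(nucleus_radius = 12,
                       nucleolus_radius = 4.5, nucleolus_radius_sd = 0.2,
                       nucleolus_friction = 1,
                       n_droplets = 55, droplet_radius = 0.9,
                       droplet_radius_sd = 0.01, droplet_friction = 0.55,
                       n_obstacles = 875, obstacle_radius = 0.85,
                       obstacle_radius_sd = 0.4, obstacle_radius_min = 0.05,
                       obstacle_friction = 5,
                       k_confine = 30, k_hard = 30, k_soft = 10, gamma = 1,
                       D0 = 0.01, alpha_act = 0.11, reference_radius = 4.5,
                       dt = 0.01, sample_dt = 300,
                       transition_time_h = 12, anchored_fraction = 0.4,
                       activity_multiplier = 1.8,
                       tether_theta = 1, tether_sigma = 0.0707,
                       tether_cap = 0.1, drift_cap = 0.5,
                       obstacle_scale = 1) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  pos_keys <- c("nucleus_radius", "nucleolus_radius", "nucleolus_friction",
                "droplet_radius", "droplet_friction", "obstacle_radius",
                "obstacle_friction", "gamma", "dt", "sample_dt",
                "reference_radius", "obstacle_scale", "drift_cap")
  for (k in pos_keys)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stop("config error: '", k, "' must be a positive number")
  nn_keys <- c("nucleolus_radius_sd", "droplet_radius_sd", "obstacle_radius_sd",
               "obstacle_radius_min", "k_confine", "k_hard", "k_soft", "D0",
               "alpha_act", "transition_time_h", "tether_theta",
               "tether_sigma", "tether_cap")
  for (k in nn_keys)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] < 0)
      stop("config error: '", k, "' must be a non-negative number")
  for (k in c("n_droplets", "n_obstacles"))
    if (cfg[[k]] < 0 || cfg[[k]] != round(cfg[[k]]))
      stop("config error: '", k, "' must be a non-negative integer")
  if (cfg$anchored_fraction < 0 || cfg$anchored_fraction > 1)
    stop("config error: 'anchored_fraction' must be in [0, 1]")
  if (cfg$activity_multiplier <= 0)
    stop("config error: 'activity_multiplier' must be positive")
  if (cfg$obstacle_scale > 1)
    stop("config error: 'obstacle_scale' must be in (0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  nucleus R = %g um; %d droplets, %d obstacles + 1 nucleolus\n",
              x$nucleus_radius, x$n_droplets, x$n_obstacles))
  cat(sprintf("  dt = %g s, sampling every %g s, obstacle_scale = %g\n",
              x$dt, x$sample_dt, x$obstacle_scale))
  invisible(x)
}

# effective obstacle count/radius under scaled-down mode (volume preserving)
.scaled_obstacles <- function(cfg) {
  n <- max(0L, as.integer(round(cfg$n_obstacles * cfg$obstacle_scale)))
  fac <- if (cfg$obstacle_scale < 1) cfg$obstacle_scale^(-1/3) else 1
  list(n = n, radius = cfg$obstacle_radius * fac,
       radius_sd = cfg$obstacle_radius_sd * fac,
       radius_min = cfg$obstacle_radius_min * fac)
}

#' Initialise a simulation scene
#'
#' Places one nucleolus, the droplets and the obstacles uniformly at random
#' inside the nucleus (agent fully inside the membrane), redrawing droplet
#' positions until no droplet-droplet contact remains.  Obstacle radii are
#' truncated-Gaussian.  Reproducible for a given seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; if `NULL` the current RNG stream is used.
#' @param max_retries placement retries per droplet before a packing error.
#' @param relax seconds of athermal overlap relaxation (droplets repelling
#'   softly instead of coalescing) applied after random placement, so
#'   dynamics start from a configuration free of placement overlaps; 0
#'   disables it.
#' @return An object of class `sim_state`: a list with elements `t` (s),
#'   `nucleus_radius`, `agents` (data frame with id, kind, x, y, z, radius,
#'   friction, anchored, anchor/tether offsets), `events`, `activity`,
#'   `config`, `seed`.
#' @export
init_scene <- function(config = sim_config(), seed = NULL, max_retries = 1000,
                       relax = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  R <- config$nucleus_radius
  obs <- .scaled_obstacles(config)

  draw_pos <- function(r) {
    # uniform in the ball of radius max(0, R - r)
    rmax <- max(R - r, 0)
    repeat {
      p <- runif(3, -rmax, rmax)
      if (sum(p^2) <= rmax^2) return(p)
    }
  }

  n_tot <- 1L + config$n_droplets + obs$n
  pos <- matrix(0, n_tot, 3)
  rad <- numeric(n_tot)
  kind <- character(n_tot)
  fric <- numeric(n_tot)

  # nucleolus
  rad[1] <- max(rnorm(1, config$nucleolus_radius, config$nucleolus_radius_sd),
                0.5)
  pos[1, ] <- draw_pos(rad[1])
  kind[1] <- "nucleolus"
  fric[1] <- config$nucleolus_friction

  # droplets: no initial droplet-droplet contact
  idx <- 1L
  if (config$n_droplets > 0) {
    for (i in seq_len(config$n_droplets)) {
      r <- max(rnorm(1, config$droplet_radius, config$droplet_radius_sd), 0.05)
      placed <- FALSE
      for (tryi in seq_len(max_retries)) {
        p <- draw_pos(r)
        ok <- TRUE
        if (i > 1) {
          prev <- (idx - i + 2):idx
          dd <- sqrt(colSums((t(pos[prev, , drop = FALSE]) - p)^2))
          ok <- all(dd > rad[prev] + r)
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) stop("packing error: could not place droplets without contact")
      idx <- idx + 1L
      pos[idx, ] <- p
      rad[idx] <- r
      kind[idx] <- "droplet"
      fric[idx] <- config$droplet_friction
    }
  }

  # obstacles: truncated Gaussian radii, free placement
  if (obs$n > 0) {
    for (i in seq_len(obs$n)) {
      r <- max(rnorm(1, obs$radius, obs$radius_sd), obs$radius_min)
      idx <- idx + 1L
      pos[idx, ] <- draw_pos(r)
      rad[idx] <- r
      kind[idx] <- "obstacle"
      fric[idx] <- config$obstacle_friction
    }
  }

  agents <- data.frame(
    id = seq_len(n_tot), kind = kind,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    radius = rad, friction = fric, anchored = FALSE,
    ax = 0, ay = 0, az = 0, tx = 0, ty = 0, tz = 0,
    stringsAsFactors = FALSE)

  state <- structure(list(
    t = 0, nucleus_radius = R, agents = agents,
    events = empty_events(), activity = NA_real_, config = config,
    seed = if (is.null(seed)) NA_integer_ else seed,
    next_id = n_tot + 1L, transitioned = FALSE,
    scaled = config$obstacle_scale < 1),
    class = "sim_state")

  # settle placement overlaps so dynamics start from a contact-consistent
  # configuration
  if (relax > 0) state <- .relax_overlaps(state, relax)
  state
}

empty_events <- function() {
  data.frame(time = numeric(0), id_a = integer(0), id_b = integer(0),
             merged_id = integer(0), merged_radius = numeric(0))
}

#' @export
print.sim_state <- function(x, ...) {
  tab <- table(x$agents$kind)
  cat(sprintf("Simulation state at t = %.1f s (nucleus R = %g um)\n",
              x$t, x$nucleus_radius))
  cat("  agents:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  coalescence events: %d; activity A = %s\n",
              nrow(x$events), format(x$activity)))
  invisible(x)
}

#' Detect droplet-droplet contacts
#'
#' Returns exactly the pairs of droplets whose center distance does not
#' exceed the sum of their radii, using a linked-cell spatial grid (identical
#' results to an all-pairs scan).
#'
#' @param state a `sim_state`.
#' @return Data frame with droplet ids `id_a`, `id_b` (one row per contact).
#' @export
detect_collisions <- function(state) {
  ag <- state$agents
  d <- ag[ag$kind == "droplet", , drop = FALSE]
  if (nrow(d) < 2)
    return(data.frame(id_a = integer(0), id_b = integer(0)))
  prs <- cpp_contact_pairs(as.matrix(d[, c("x", "y", "z")]), d$radius)
  data.frame(id_a = d$id[prs[, 1]], id_b = d$id[prs[, 2]])
}

# shared marshalling into the compiled core
.run_core <- function(state, t_end, dt, law, field, sample_dt,
                      stop_at_count = 0L, forces_on = TRUE,
                      coalesce_on = TRUE, record_tracks = FALSE,
                      droplet_repel = FALSE) {
  ag <- state$agents
  cfg <- state$config
  res <- cpp_run_sim(
    as.matrix(ag[, c("x", "y", "z")]), ag$radius, .kind_code(ag$kind),
    ag$friction, ag$anchored, as.matrix(ag[, c("ax", "ay", "az")]),
    as.matrix(ag[, c("tx", "ty", "tz")]), as.integer(ag$id),
    state$nucleus_radius, state$t, dt, t_end,
    law$D0 + law$alpha_act * law$activity, law$reference_radius,
    field$k_confine, field$k_soft, field$k_hard,
    cfg$tether_theta, cfg$tether_sigma, cfg$tether_cap,
    sample_dt, as.integer(stop_at_count), as.integer(state$next_id),
    forces_on, coalesce_on, record_tracks, cfg$drift_cap, droplet_repel)

  agents <- data.frame(
    id = res$id, kind = .kind_levels[res$kind + 1L],
    x = res$pos[, 1], y = res$pos[, 2], z = res$pos[, 3],
    radius = res$radius, friction = res$friction, anchored = res$anchored,
    ax = res$anchor_offset[, 1], ay = res$anchor_offset[, 2],
    az = res$anchor_offset[, 3],
    tx = res$tether[, 1], ty = res$tether[, 2], tz = res$tether[, 3],
    stringsAsFactors = FALSE)
  ev <- as.data.frame(res$events)
  names(ev) <- c("time", "id_a", "id_b", "merged_id", "merged_radius")
  state$agents <- agents
  state$t <- res$t
  state$events <- rbind(state$events, ev)
  state$next_id <- res$next_id
  samples <- as.data.frame(res$samples)
  attr(samples, "stopped") <- res$stopped
  list(state = state, samples = samples,
       tracks = if (record_tracks) res$tracks else NULL)
}

#' Advance the simulation by one step
#'
#' A single explicit Euler-Maruyama step of the force balance: each free
#' agent moves by the capped overlap-penalty drift plus an isotropic Gaussian
#' increment with per-axis variance `2 * D_i * dt`; anchored obstacles follow
#' the nucleolus with a small tether fluctuation; droplet contacts are then
#' resolved by iterated coalescence.
#'
#' @param state a `sim_state`.
#' @param dt time step, s.
#' @param law a [diffusion_law()].
#' @param field a [force_field()].
#' @return The updated `sim_state`.
#' @export
sim_step <- function(state, dt, law = diffusion_law(), field = force_field()) {
  if (dt <= 0) stop("dt must be positive")
  .run_core(state, state$t + dt, dt, law, field, sample_dt = dt)$state
}

#' Run the simulation to a target time
#'
#' Integrates the scene until `t_end`, recording droplet count and mean
#' droplet radius every `sample_dt` seconds plus the coalescence event log.
#'
#' @inheritParams sim_step
#' @param t_end target time, s.
#' @param sample_dt sampling cadence, s.
#' @param stop_at_count if positive, stop early once the droplet count falls
#'   to this value.
#' @param record_tracks record droplet positions at each sample (valid while
#'   no coalescence occurs; used for calibration and diffusion checks).
#' @return List with `state` (final `sim_state`), `samples` (data frame
#'   `t`, `n_droplets`, `mean_radius`) and optionally `tracks`
#'   (3 x n_droplets x n_samples array).
#' @export
run_sim <- function(state, t_end, dt = state$config$dt,
                    law = diffusion_law(), field = force_field(),
                    sample_dt = state$config$sample_dt,
                    stop_at_count = 0, record_tracks = FALSE) {
  .run_core(state, t_end, dt, law, field, sample_dt,
            stop_at_count = stop_at_count, record_tracks = record_tracks)
}
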