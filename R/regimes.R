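#' Cytoplasmic activity catalog
#'
#' Activity levels per biological condition and growth stage.  SN-stage
#' values are experimental: control 1, nocodazole 1.9, FMN2-knockout 0.2.
#' The NSN control value is 0.55; NSN values for the other conditions are the
#' SN value divided by the 1.8 NSN-to-SN activity ratio.
#'
#' @param condition one of `"control"`, `"nocodazole"`, `"fmn2ko"`.
#' @param stage `"NSN"` or `"SN"`.
#' @return Dimensionless activity `A`.
#' @examples
#' condition_activity("control", "SN")    # 1
#' condition_activity("fmn2ko", "SN")     # 0.2
#' condition_activity("nocodazole", "NSN") # 1.9 / 1.8
#' @export
condition_activity <- function(condition = c("control", "nocodazole", "fmn2ko"),
                               stage = c("NSN", "SN")) {
  sn <- c(control = 1, nocodazole = 1.9, fmn2ko = 0.2)
  if (length(condition) != 1 || !condition %in% names(sn))
    stop("catalog error: no catalogued activity for condition '",
         paste(condition, collapse = ","), "'")
  stage <- match.arg(stage)
  if (stage == "SN") unname(sn[condition])
  else if (condition == "control") 0.55
  else unname(sn[condition]) / 1.8
}

#' Simulation series specification
#'
#' Series 1 is NSN-like (dispersed obstacles, constant activity, 20 h);
#' series 2 is the NSN-to-SN transition (at 12 h, 40% of the obstacles
#' nearest the nucleolus anchor to it and activity is multiplied by 1.8;
#' horizon 40 h); series 3 is SN-like (40% anchored from the start, constant
#' activity, 20 h).  Longer-term dynamics are extrapolated from a decreasing
#' exponential fitted to the last `tail_fit_window_h` hours.
#'
#' @param series 1, 2 or 3.
#' @param transition_time_h transition time for series 2, hours.
#' @param anchored_fraction fraction of obstacles anchored.
#' @param activity_multiplier activity factor applied at the transition.
#' @param horizon_h simulated hours (defaults: 20 for series 1/3, 40 for 2).
#' @param tail_fit_window_h width of the tail-fit window, hours.
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(series = 2, transition_time_h = 12,
                        anchored_fraction = 0.4, activity_multiplier = 1.8,
                        horizon_h = if (series == 2) 40 else 20,
                        tail_fit_window_h = 5) {
  if (!series %in% 1:3) stop("series must be 1, 2 or 3")
  if (anchored_fraction < 0 || anchored_fraction > 1)
    stop("anchored_fraction must be in [0, 1]")
  if (series == 2 && transition_time_h >= horizon_h)
    stop("transition_time_h must be before the horizon")
  structure(list(series = as.integer(series),
                 transition_time_h = transition_time_h,
                 anchored_fraction = anchored_fraction,
                 activity_multiplier = activity_multiplier,
                 horizon_h = horizon_h,
                 tail_fit_window_h = tail_fit_window_h),
            class = "series_spec")
}

# Anchors the given fraction of obstacles (nearest the nucleolus surface,
# ties by id) and compacts them radially into a packing shell around the
# nucleolus, preserving the rank order of distances and each obstacle's
# angular position.  Offsets relative to the nucleolus are then recorded.
.anchor_obstacles <- function(state, fraction, packing = 0.55) {
  ag <- state$agents
  nuc <- which(ag$kind == "nucleolus")
  obs <- which(ag$kind == "obstacle")
  n_anchor <- round(length(obs) * fraction)
  if (n_anchor == 0 || length(nuc) != 1) return(state)
  np <- c(ag$x[nuc], ag$y[nuc], ag$z[nuc])
  rn <- ag$radius[nuc]
  d_center <- sqrt((ag$x[obs] - np[1])^2 + (ag$y[obs] - np[2])^2 +
                   (ag$z[obs] - np[3])^2)
  d_surface <- d_center - rn
  ord <- obs[order(d_surface, ag$id[obs])]
  sel <- ord[seq_len(n_anchor)]

  # packing shell radius from the total anchored volume at the given fraction
  v_anchor <- sum((4 / 3) * pi * ag$radius[sel]^3)
  R_pack <- (rn^3 + v_anchor / (packing * (4 / 3) * pi))^(1 / 3)
  # volume-uniform radial targets within the shell, in distance-rank order
  k <- seq_len(n_anchor)
  r_target <- (rn^3 + (k - 0.5) / n_anchor * (R_pack^3 - rn^3))^(1 / 3)

  for (j in seq_len(n_anchor)) {
    i <- sel[j]
    dir <- c(ag$x[i], ag$y[i], ag$z[i]) - np
    dn <- sqrt(sum(dir^2))
    dir <- if (dn > 1e-9) dir / dn else c(1, 0, 0)
    tgt <- (r_target[j] + ag$radius[i] * 0.0)  # center placed at shell radius
    newp <- np + dir * tgt
    ag$x[i] <- newp[1]; ag$y[i] <- newp[2]; ag$z[i] <- newp[3]
    ag$ax[i] <- newp[1] - np[1]
    ag$ay[i] <- newp[2] - np[2]
    ag$az[i] <- newp[3] - np[3]
    ag$tx[i] <- 0; ag$ty[i] <- 0; ag$tz[i] <- 0
    ag$anchored[i] <- TRUE
  }
  state$agents <- ag
  state
}

#' Apply the NSN-to-SN transition
#'
#' Anchors the `anchored_fraction` of obstacles closest to the nucleolus
#' surface (ties broken by id) to the nucleolus, compacting them into a shell
#' around it, and multiplies the cytoplasmic activity by
#' `activity_multiplier` (1.8).  A short athermal settling pass (droplets
#' repelling, no coalescence) then resolves the overlaps the compaction
#' created, so the rearrangement itself does not fuse droplets.  Calling the
#' transition twice on the same state is an error.
#'
#' @param state a `sim_state`.
#' @param spec a [series_spec()].
#' @param relax settling seconds after compaction (0 disables).
#' @return The transitioned `sim_state` (with updated `activity`).
#' @export
apply_transition <- function(state, spec = series_spec(2), relax = 5) {
  if (isTRUE(state$transitioned))
    stop("state error: transition already applied")
  state <- .anchor_obstacles(state, spec$anchored_fraction)
  if (relax > 0) state <- .relax_overlaps(state, relax)
  if (!is.na(state$activity))
    state$activity <- state$activity * spec$activity_multiplier
  state$transitioned <- TRUE
  state
}

# athermal drift-only settling with droplets repelling softly: resolves the
# overlaps created by placement or by obstacle compaction without letting
# the rearrangement itself fuse droplets
.relax_overlaps <- function(state, relax) {
  cfg <- state$config
  zero <- diffusion_law(0, 0, 0, cfg$reference_radius)
  fld <- force_field(cfg$k_confine, cfg$k_hard, cfg$k_soft, cfg$gamma)
  t0 <- state$t
  state <- .run_core(state, t0 + relax, 0.01, zero, fld, relax,
                     coalesce_on = FALSE, droplet_repel = TRUE)$state
  state$t <- t0
  state
}

#' Run a simulation series
#'
#' Initialises a scene, runs the condition's activity program for the
#' series' horizon and summarises the trajectory (droplet count and mean
#' droplet radius every `sample_dt` seconds).
#'
#' @param spec a [series_spec()].
#' @param condition,stage condition name and starting stage passed to
#'   [condition_activity()]; alternatively supply `activity` directly.
#' @param activity starting activity (overrides the catalog if given).
#' @param seed integer seed (one seeded generator drives the whole run).
#' @param config a [sim_config()]; `config$dt` and `config$sample_dt` set the
#'   integration and sampling cadence.
#' @param stop_at_count optional early stop when the droplet count reaches
#'   this value (0 = run the full horizon).
#' @return A `trajectory_summary` data frame with columns `time_h`,
#'   `n_droplets`, `mean_radius_um`, `activity`, and metadata attributes
#'   (seed, dt, series, condition, scaled flag).
#' @export
run_series <- function(spec = series_spec(2), condition = "control",
                       stage = "NSN", activity = NULL, seed = 1,
                       config = sim_config(), stop_at_count = 0) {
  stopifnot(inherits(spec, "series_spec"))
  A0 <- if (is.null(activity)) condition_activity(condition, stage) else activity
  set.seed(seed)
  state <- init_scene(config)
  state$activity <- A0
  state$seed <- seed
  if (spec$series == 3) {
    state <- .anchor_obstacles(state, spec$anchored_fraction)
    state <- .relax_overlaps(state, 5)
  }

  field <- force_field(config$k_confine, config$k_hard, config$k_soft,
                       config$gamma)
  law <- function(A) diffusion_law(config$D0, config$alpha_act, A,
                                   config$reference_radius)
  horizon_s <- spec$horizon_h * 3600
  samples <- NULL
  act_col <- NULL

  if (spec$series == 2) {
    t_switch <- spec$transition_time_h * 3600
    seg1 <- run_sim(state, t_switch, dt = config$dt, law = law(A0),
                    field = field, sample_dt = config$sample_dt,
                    stop_at_count = stop_at_count)
    samples <- seg1$samples
    act_col <- rep(A0, nrow(samples))
    state <- seg1$state
    if (!attr(seg1$samples, "stopped")) {
      state <- apply_transition(state, spec)
      A1 <- state$activity
      seg2 <- run_sim(state, horizon_s, dt = config$dt, law = law(A1),
                      field = field, sample_dt = config$sample_dt,
                      stop_at_count = stop_at_count)
      state <- seg2$state
      s2 <- seg2$samples[-1, , drop = FALSE]  # drop duplicated switch sample
      samples <- rbind(samples, s2)
      act_col <- c(act_col, rep(A1, nrow(s2)))
    }
  } else {
    seg <- run_sim(state, horizon_s, dt = config$dt, law = law(A0),
                   field = field, sample_dt = config$sample_dt,
                   stop_at_count = stop_at_count)
    state <- seg$state
    samples <- seg$samples
    act_col <- rep(A0, nrow(samples))
  }

  out <- data.frame(time_h = samples$t / 3600,
                    n_droplets = samples$n_droplets,
                    mean_radius_um = samples$mean_radius,
                    activity = act_col)
  structure(out, class = c("trajectory_summary", "data.frame"),
            seed = seed, dt = config$dt, series = spec$series,
            condition = condition, start_activity = A0,
            scaled = config$obstacle_scale < 1 || config$dt > 0.01,
            spec = spec, events = state$events, final_state = state)
}

#' Re-origin a trajectory at a reference droplet count
#'
#' Shifts time so that `t = 0` is the first sample at which the droplet
#' count is at or below `n0` (45 by default, the common alignment count).
#' If the trajectory never reaches `n0` it is returned unchanged with a
#' warning and an `aligned = FALSE` attribute.
#'
#' @param summary a `trajectory_summary`.
#' @param n0 alignment droplet count.
#' @return The time-shifted summary (attribute `aligned` records success).
#' @export
align_at_count <- function(summary, n0 = 45) {
  i <- which(summary$n_droplets <= n0)
  if (!length(i)) {
    warning("alignment error: trajectory never reaches ", n0, " droplets")
    attr(summary, "aligned") <- FALSE
    return(summary)
  }
  summary$time_h <- summary$time_h - summary$time_h[i[1]]
  attr(summary, "aligned") <- TRUE
  summary
}

#' Time to reach a target droplet count
#'
#' Returns the first crossing time if the count reaches `n` within the
#' horizon.  Otherwise a decreasing exponential `c(t) = a * exp(-t / tau) + 1`
#' (floor fixed at one droplet, the absorbing state) is fitted to the last
#' `tail_fit_window_h` hours and the extrapolated crossing is returned;
#' crossings beyond 100 h are flagged as capped.  For series 2 the time
#' measured from the transition is reported as well.
#'
#' @param summary a `trajectory_summary`.
#' @param n target droplet count (default 4).
#' @param spec a [series_spec()]; defaults to the spec stored in `summary`.
#' @return An object of class `time_to_n`: list with `hours`,
#'   `hours_from_transition` (series 2), `extrapolated`, `capped`,
#'   `degenerate` and the tail-fit parameters when extrapolated.
#' @export
time_to_n_droplets <- function(summary, n = 4, spec = attr(summary, "spec")) {
  if (is.null(spec)) spec <- series_spec(1)
  res <- list(n = n, extrapolated = FALSE, capped = FALSE, degenerate = FALSE,
              tau_h = NA_real_, a = NA_real_)
  hit <- which(summary$n_droplets <= n)
  if (length(hit)) {
    res$hours <- summary$time_h[hit[1]]
  } else {
    res$extrapolated <- TRUE
    t_last <- max(summary$time_h)
    tail_df <- summary[summary$time_h >= t_last - spec$tail_fit_window_h, ,
                       drop = FALSE]
    y <- tail_df$n_droplets - 1          # exponential above the 1-droplet floor
    keep <- y > 0
    fitok <- FALSE
    if (sum(keep) >= 3 && var(tail_df$n_droplets[keep]) > 0) {
      fit <- lm(log(y[keep]) ~ tail_df$time_h[keep])
      slope <- coef(fit)[2]
      if (is.finite(slope) && slope < 0) {
        tau <- -1 / slope
        a <- exp(coef(fit)[1])
        res$tau_h <- unname(tau)
        res$a <- unname(a)
        res$hours <- unname(tau * log(a / (n - 1)))
        res$capped <- res$hours > 100
        fitok <- TRUE
      }
    }
    if (!fitok) {
      res$degenerate <- TRUE
      res$hours <- NA_real_
    }
  }
  if (!is.null(attr(summary, "series")) && attr(summary, "series") == 2)
    res$hours_from_transition <- res$hours - spec$transition_time_h
  class(res) <- "time_to_n"
  res
}

#' @export
print.time_to_n <- function(x, ...) {
  lab <- if (isTRUE(x$capped)) "> 100 h"
  else if (is.na(x$hours)) "indeterminate (degenerate tail)"
  else sprintf("%.1f h%s", x$hours, if (x$extrapolated) " (extrapolated)" else "")
  cat(sprintf("Time to %d droplets: %s\n", x$n, lab))
  if (!is.null(x$hours_from_transition) && !is.na(x$hours))
    cat(sprintf("  from the transition: %.1f h\n", x$hours_from_transition))
  invisible(x)
}
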