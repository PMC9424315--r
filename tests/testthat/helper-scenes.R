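# shared fixtures built in code

# tiny fast configuration for unit tests of the integrator and regimes
tiny_config <- function(...) {
  base <- list(n_droplets = 12, n_obstacles = 40, dt = 0.05, sample_dt = 10)
  do.call(sim_config, modifyList(base, list(...)))
}

# all-pairs contact oracle (the independent route detect_collisions must match)
brute_contacts <- function(pos, rad) {
  n <- nrow(pos)
  out <- NULL
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= rad[i] + rad[j])
        out <- rbind(out, c(i, j))
    }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# naive double-loop temporal MSD oracle
brute_msd <- function(pos, dt, kmax) {
  vapply(seq_len(kmax), function(k) {
    n <- nrow(pos)
    mean(vapply(seq_len(n - k), function(i)
      sum((pos[i + k, ] - pos[i, ])^2), numeric(1)))
  }, numeric(1))
}

total_droplet_volume <- function(state) {
  d <- state$agents[state$agents$kind == "droplet", ]
  sum(d$radius^3)
}
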