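test_that("the activity catalog matches the condition table", {
  expect_equal(condition_activity("control", "SN"), 1)
  expect_equal(condition_activity("nocodazole", "SN"), 1.9)
  expect_equal(condition_activity("fmn2ko", "SN"), 0.2)
  expect_equal(condition_activity("control", "NSN"), 0.55)
  expect_equal(condition_activity("nocodazole", "NSN"), 1.9 / 1.8)
  expect_equal(condition_activity("fmn2ko", "NSN"), 0.2 / 1.8)
  expect_error(condition_activity("taxol", "SN"), "catalog error")
})

test_that("the transition anchors the obstacles nearest the nucleolus", {
  cfg <- sim_config()
  st <- init_scene(cfg, seed = 31, relax = 0)
  st$activity <- 0.55
  # reference: brute-force sort by center-to-nucleolus-surface distance
  ag <- st$agents
  nuc <- ag[ag$kind == "nucleolus", ]
  obs <- ag[ag$kind == "obstacle", ]
  dsurf <- sqrt((obs$x - nuc$x)^2 + (obs$y - nuc$y)^2 + (obs$z - nuc$z)^2) -
    nuc$radius
  expected_ids <- obs$id[order(dsurf, obs$id)][1:350]

  out <- apply_transition(st, series_spec(2), relax = 0)
  anch <- out$agents[out$agents$anchored, ]
  expect_equal(nrow(anch), 350)          # 40% of 875
  expect_setequal(anch$id, expected_ids)
  expect_equal(out$activity, 0.55 * 1.8)
  # non-selected agents untouched
  free <- out$agents[!out$agents$anchored, ]
  before <- ag[match(free$id, ag$id), ]
  expect_equal(free$x, before$x)
  expect_equal(free$radius, before$radius)
  # anchored obstacles sit around the nucleolus, offsets recorded
  d_after <- sqrt(anch$ax^2 + anch$ay^2 + anch$az^2)
  expect_true(all(d_after >= nuc$radius - 1e-9))
  expect_error(apply_transition(out, series_spec(2)), "state error")
})

test_that("series programs drive activity and anchoring as specified", {
  cfg <- tiny_config(n_droplets = 6, n_obstacles = 30, sample_dt = 60)
  # series 1: constant activity throughout
  s1 <- run_series(series_spec(1, horizon_h = 0.05), activity = 0.55,
                   seed = 1, config = cfg)
  expect_true(all(s1$activity == 0.55))
  expect_equal(s1$n_droplets[1], 6)
  expect_true(all(diff(s1$n_droplets) <= 0))
  # series 2: a single 1.8x jump at the transition
  sp2 <- series_spec(2, transition_time_h = 0.02, horizon_h = 0.05)
  s2 <- run_series(sp2, activity = 0.55, seed = 1, config = cfg)
  expect_equal(sort(unique(s2$activity)), c(0.55, 0.99))
  expect_equal(s2$activity[s2$time_h > 0.021],
               rep(0.99, sum(s2$time_h > 0.021)))
  # series 3: anchored obstacles from the start
  s3 <- run_series(series_spec(3, horizon_h = 0.02), activity = 1,
                   seed = 1, config = cfg)
  fin <- attr(s3, "final_state")
  expect_equal(sum(fin$agents$anchored), round(0.4 * 30))
})

test_that("alignment re-origins time at the reference count", {
  tsum <- structure(
    data.frame(time_h = 0:10, n_droplets = c(55, 52, 48, 45, 40, 30, 20,
                                             10, 8, 5, 4),
               mean_radius_um = 1, activity = 1),
    class = c("trajectory_summary", "data.frame"))
  al <- align_at_count(tsum, 45)
  expect_equal(al$time_h[4], 0)
  expect_true(attr(al, "aligned"))
  expect_true(all(diff(al$n_droplets) <= 0))
  # already at the reference count: unchanged
  t2 <- tsum[tsum$n_droplets <= 45, ]
  expect_equal(align_at_count(t2, 45)$time_h, t2$time_h - t2$time_h[1])
  # never reaches the count: warning + flag
  t3 <- tsum[1:2, ]
  expect_warning(al3 <- align_at_count(t3, 45), "alignment")
  expect_false(attr(al3, "aligned"))
})

test_that("time to a target count crosses directly or extrapolates the tail", {
  mk <- function(time_h, n) structure(
    data.frame(time_h = time_h, n_droplets = n, mean_radius_um = 1,
               activity = 1),
    class = c("trajectory_summary", "data.frame"))
  # direct crossing
  tt <- time_to_n_droplets(mk(seq(0, 20, 0.2), pmax(4, 55 - seq(0, 100, 1))),
                           4, series_spec(1))
  expect_false(tt$extrapolated)
  expect_equal(tt$hours, 10.2)
  # exponential tail with known timescale: analytic crossing within 2%
  tau_star <- 10
  tgrid <- seq(0, 20, 1 / 12)
  counts <- 45 * exp(-tgrid / tau_star) + 1
  tt <- time_to_n_droplets(mk(tgrid, counts), 4, series_spec(1))
  expect_true(tt$extrapolated)
  expect_equal(tt$hours, tau_star * log(45 / 3), tolerance = 0.02)
  # constant tail cannot be extrapolated
  tt <- time_to_n_droplets(mk(seq(0, 20, 0.5), rep(10, 41)), 4, series_spec(1))
  expect_true(tt$degenerate)
  expect_true(is.na(tt$hours))
})
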