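test_that("temporal MSD matches closed forms and the double-loop oracle", {
  # stationary track: identically zero
  tm <- seq(0, 10, 0.5)
  st <- track(tm, matrix(1.5, length(tm), 2))
  expect_true(all(temporal_msd(st)$msd == 0))
  # ballistic: msd(tau) = (v tau)^2
  v <- 0.3
  bal <- track(tm, cbind(v * tm, 0))
  m <- temporal_msd(bal, max_lag = 5)
  expect_equal(m$msd, (v * m$lags)^2, tolerance = 1e-12)
  # random 10-point track equals the naive oracle exactly
  set.seed(1)
  pos <- matrix(rnorm(30), 10, 3)
  tr <- track(seq(0, 4.5, 0.5), pos)
  m <- temporal_msd(tr, max_lag = 2)
  expect_equal(m$msd, brute_msd(pos, 0.5, 4), tolerance = 1e-12)
  expect_error(temporal_msd(track(0, matrix(0, 1, 2))), "at least 2")
})

test_that("drift correction subtracts the reference trajectory", {
  tm <- seq(0, 20, 0.5)
  set.seed(2)
  inc <- matrix(rnorm(length(tm) * 2, sd = 0.1), ncol = 2)
  pure <- apply(inc, 2, cumsum)
  drift <- cbind(0.2 * tm, -0.1 * tm)
  tr_drifted <- track(tm, pure + drift, drift_reference = drift)
  tr_pure <- track(tm, pure)
  expect_equal(temporal_msd(tr_drifted)$msd, temporal_msd(tr_pure)$msd,
               tolerance = 1e-12)
  # D_eff invariant under rigid translation
  f1 <- effective_diffusion(temporal_msd(tr_pure, 20), radius = 1, n_points = 20)
  tr_shift <- track(tm, pure + 5)
  f2 <- effective_diffusion(temporal_msd(tr_shift, 20), radius = 1, n_points = 20)
  expect_equal(f1$D_eff, f2$D_eff, tolerance = 1e-12)
})

test_that("the anomalous exponent fit recovers known exponents", {
  lags <- seq(0.5, 20, 0.5)
  # noiseless power law
  f <- structure(list(lags = lags, msd = 0.3 * lags^0.7, dim = 2),
                 class = "msd_fit")
  expect_equal(fit_alpha(f)$alpha, 0.7, tolerance = 1e-6)
  # ballistic
  f$msd <- 0.1 * lags^2
  expect_equal(fit_alpha(f)$alpha, 2, tolerance = 1e-6)
  expect_error(fit_alpha(structure(list(lags = lags, msd = lags * NaN, dim = 2),
                                   class = "msd_fit")), "non-finite")
  # Brownian synthetic tracks: mean alpha within 1 +/- 0.05
  set.seed(3)
  alphas <- replicate(250, {
    tr <- gen_track(n_steps = 80, dt = 0.5, D = 0.16, alpha = 1, dim = 2)
    fit_alpha(temporal_msd(tr, max_lag = 5))$alpha
  })
  expect_equal(mean(alphas), 1, tolerance = 0.05)
})

test_that("alpha recovery holds across the subdiffusive generator grid", {
  set.seed(4)
  for (a_star in c(0.5, 0.7, 1.0)) {
    alphas <- replicate(60, {
      tr <- gen_track(n_steps = 60, dt = 0.5, D = 0.1, alpha = a_star, dim = 2)
      fit_alpha(temporal_msd(tr, max_lag = 7.5))$alpha
    })
    expect_equal(mean(alphas), a_star, tolerance = 0.1)
  }
})

test_that("effective diffusion uses slope/(2d) and the (3/2)*pi*r norm", {
  lags <- seq(0.5, 20, 0.5)
  f <- structure(list(lags = lags, msd = 4 * 0.1 * lags, dim = 2, radius = 2),
                 class = "msd_fit")
  fe <- effective_diffusion(f)
  expect_equal(fe$D_eff, 0.1, tolerance = 1e-12)
  expect_equal(fe$D_eff_normalized, 0.1 * 3 * pi, tolerance = 1e-12)
  # zero motion -> zero
  f$msd <- rep(0, length(lags))
  expect_equal(effective_diffusion(f)$D_eff, 0)
  expect_error(effective_diffusion(structure(
    list(lags = lags[1:10], msd = lags[1:10], dim = 2, radius = 1),
    class = "msd_fit")), "window error")
  # ensemble recovery of a known D from the Brownian generator over the
  # standard 40-point window
  set.seed(5)
  msum <- 0
  for (i in 1:300) {
    tr <- gen_track(n_steps = 120, dt = 0.5, D = 0.16, alpha = 1, dim = 2)
    msum <- msum + temporal_msd(tr, max_lag = 20)$msd
  }
  m <- list(lags = seq(0.5, 20, 0.5), msd = msum / 300, dim = 2, radius = 1)
  class(m) <- "msd_fit"
  fe <- effective_diffusion(m, n_points = 40)
  expect_equal(fe$D_eff, 0.16, tolerance = 0.05)
})

test_that("count and size curves follow the event log", {
  init <- data.frame(id = 1:45, radius = 0.9)
  # no events: flat 100%
  flat <- count_and_size_curves(empty_events <- data.frame(
    time = numeric(0), id_a = integer(0), id_b = integer(0),
    merged_id = integer(0), merged_radius = numeric(0)), init)
  expect_equal(flat$pct_initial, 100)
  # 9 fusions from 45 -> 80%
  ev <- data.frame(time = 1:9, id_a = 1:9, id_b = 10:18,
                   merged_id = 46:54, merged_radius = 0.9 * 2^(1 / 3))
  cc <- count_and_size_curves(ev, init)
  expect_equal(cc$n_droplets[nrow(cc)], 36)
  expect_equal(cc$pct_initial[nrow(cc)], 80)
  # merged surface lies between each parent's and the sum of parents'
  s_parent <- pi * 0.9^2
  s_merged <- pi * (0.9 * 2^(1 / 3))^2
  expect_gt(s_merged, s_parent)
  expect_lt(s_merged, 2 * s_parent)
})
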