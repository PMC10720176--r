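# Smoothing, berry selection, normalisation and ripening descriptors.

make_series <- function(times, V, H = rep(NA_real_, length(times)),
                        label = 1, coverage = 1) {
  list(label = label, times = times, V = V, H = H,
       V_smooth = moving_median(times, V, 8),
       coverage = coverage,
       mape_fit = mean(abs(V - moving_median(times, V, 8)) /
                         moving_median(times, V, 8)))
}

test_that("moving median removes spikes and preserves linear interiors", {
  t <- seq(0, 30, by = 1 / 3)
  expect_equal(moving_median(t, rep(5, length(t))), rep(5, length(t)))
  v <- rep(5, length(t)); v[40] <- 50
  expect_equal(moving_median(t, v), rep(5, length(t)))
  lin <- 2 + 0.3 * t
  sm <- moving_median(t, lin)
  interior <- t >= 4 & t <= 26
  expect_equal(sm[interior], lin[interior], tolerance = 1e-9)
})

test_that("berry selection applies coverage then a fixed-fraction MAPE drop", {
  set.seed(51)
  t <- seq(0, 30, by = 1 / 3)
  mk <- function(lab, noise) {
    v <- 100 * exp(rnorm(length(t), 0, noise))
    make_series(t, v, label = lab)
  }
  series <- lapply(1:81, function(i) mk(i, 0.002 * i))
  kept <- select_berries(series)
  expect_length(kept, 73) # 81 - floor(8.1)
  # the series with the highest realised MAPE are the ones dropped
  dropped <- setdiff(1:81, vapply(kept, function(s) s$label, numeric(1)))
  mape <- vapply(series, function(s) s$mape_fit, numeric(1))
  expect_setequal(dropped, order(mape, decreasing = TRUE)[1:8])

  low_cov <- mk(99, 0.001); low_cov$coverage <- 0.5
  expect_length(select_berries(c(series[1:5], list(low_cov))), 5)
  # noise-free cohort still loses the fixed fraction
  clean <- lapply(1:10, function(i) mk(i, 0))
  expect_length(select_berries(clean), 9)
})

test_that("normalisation produces relative and scaled values with flags", {
  t <- seq(0, 30, by = 0.5)
  v <- rep(2, length(t))
  nz <- normalize_series(t, v, v, "V")
  expect_true(nz$degenerate)
  expect_equal(nz$X_r, rep(0, length(t)))
  expect_true(all(is.na(nz$X_s)))

  # plateau 1 (days 0-8), ramp, plateau 2 (last 8 days)
  v <- approx(c(0, 8, 22, 30), c(1, 1, 2, 2), xout = t)$y
  nz <- normalize_series(t, v, v, "V")
  expect_equal(nz$X_0, 1)
  expect_equal(nz$X_max, 2)
  expect_true(all(nz$X_s >= 0 & nz$X_s <= 1))
  nz2 <- normalize_series(t, 2 * v, 2 * v, "V")
  expect_equal(nz2$X_r, nz$X_r) # scale invariance
  expect_equal(nz2$X_s, nz$X_s)
})

test_that("crossing times interpolate linearly with boundary conventions", {
  t <- 0:10
  ramp <- t / 10
  expect_equal(crossing_time(t, ramp, 0.15), 1.5)
  expect_equal(crossing_time(t, ramp + 0.5, 0.15), 0) # starts above
  expect_true(is.na(crossing_time(t, ramp * 0.1, 0.15)))
})

test_that("RD and RS follow the 15/85 crossing definitions", {
  t <- seq(0, 30, by = 1 / 3)
  # scaled linear ramp over 20 days: crossings at 3 and 17 days
  vs <- pmin(pmax(t / 20, 0), 1)
  t15 <- crossing_time(t, vs, 0.15); t85 <- crossing_time(t, vs, 0.85)
  expect_equal(t85 - t15, 14, tolerance = 1e-9)
  expect_equal((t85 - t15) / 0.7, 20, tolerance = 1e-9)
  # V_r rising linearly 0 -> 1 over those 20 days: RS = 0.7/14 = 0.05/day
  vr <- pmin(pmax(t / 20, 0), 1)
  expect_equal((approx(t, vr, t85)$y - approx(t, vr, t15)$y) / (t85 - t15),
               0.05, tolerance = 1e-9)

  # full pipeline on a plateau-ramp-plateau volume series (14-day ramp)
  v <- approx(c(0, 8, 22, 30), c(1, 1, 2, 2), xout = t)$y
  s <- make_series(t, v)
  st <- ripening_stats(s)
  expect_equal(st$RD, 14, tolerance = 0.5) # 0.7 * 14-day ramp / 0.7
  # RS = dV_r/dt across the window: the ramp slope 1/14 per day in V_r
  expect_equal(st$RS, 1 / 14, tolerance = 0.004)
  # doubling volumes changes neither RD nor RS
  s2 <- make_series(t, 2 * v)
  st2 <- ripening_stats(s2)
  expect_equal(st2$RD, st$RD)
  expect_equal(st2$RS, st$RS)
  # halving the rise amplitude halves RS at equal timing
  vh <- approx(c(0, 8, 22, 30), c(1, 1, 1.5, 1.5), xout = t)$y
  sth <- ripening_stats(make_series(t, vh))
  expect_equal(sth$RS, st$RS / 2, tolerance = 0.002)
})

test_that("the mean berry widens the apparent ripening of asynchronous cohorts", {
  t <- seq(0, 60, by = 1 / 3)
  logi <- function(onset) {
    k <- 2 * log(0.85 / 0.15) / 18
    1 + 0.6 / (1 + exp(-k * (t - onset - 9)))
  }
  same <- lapply(1:3, function(i) make_series(t, logi(15), label = i))
  mb <- mean_berry(same)
  ind <- ripening_stats(same[[1]])
  expect_equal(mb$stats$RD, ind$RD, tolerance = 1) # identical berries
  # offset by a lag comparable to the rise: mean RD exceeds individual RD
  lagged <- list(make_series(t, logi(8), label = 1),
                 make_series(t, logi(26), label = 2))
  mbl <- mean_berry(lagged)
  expect_gt(mbl$stats$RD, ripening_stats(lagged[[1]])$RD)
})

test_that("kinetics summary recovers simulated growth through the measurement chain", {
  # onsets clear of the early baseline window and plateaus reached before
  # the late one: the regime the normalisation method presumes
  cfg <- sim_config(n_berries = 12, n_frames = 165, cluster_sd = 150,
                    image_size = c(700, 700), onset_range = c(14, 26),
                    rise_days = 18, shrivel_frac = 0, jitter_sd_px = 0.5,
                    jitter_sd_deg = 0.2, jitter_sd_scale = 0, seed = 14)
  sim <- simulate_bunch(cfg)
  tracks <- sim_measured_tracks(sim)
  ks <- kinetics_summary(tracks)
  ind <- ks$summary[ks$summary$label != "mean", ]
  expect_gt(nrow(ind), 5)
  idx <- match(as.integer(ind$label), sim$berries$berry_id)
  expect_lte(median(abs(ind$RD - 18 / 0.7)), 1)
  expect_lte(median(abs(ind$t_resume - sim$berries$onset[idx])), 1)
  expect_equal(median(ind$max_rel_expansion), 0.6, tolerance = 0.05)
})
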