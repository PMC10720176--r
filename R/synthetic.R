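#' Synthetic time-lapse bunch simulator
#'
#' Generates ground-truthed berry time-lapse data with the statistical
#' structure the pipeline assumes: dozens of overlapping ellipses in a 2D
#' cluster with a fixed depth order, per-berry asynchronous plateau-
#' logistic-plateau volume growth (about +60% volume over an 18-day
#' 15-85% rise by default), a green-to-dark raw-hue transition lagging
#' growth onset, cumulative small affine camera jitter, optional abrupt
#' rotation events and non-affine rearrangements, and per-frame visibility
#' computed as the fraction of a berry's boundary not covered by berries
#' in front of it. The seed fully determines the output.
#'
#' @name synthetic
NULL

#' Simulator configuration
#'
#' @param n_berries number of berries.
#' @param n_frames number of time steps.
#' @param step_hours interval between frames (h).
#' @param image_size `c(nrow, ncol)` of the (virtual or rendered) image.
#' @param cluster_sd spatial spread of berry centres (px).
#' @param radius_range range of initial berry semi-minor radii (px).
#' @param aspect_range range of berry axis ratios (h_e / w_e).
#' @param onset_range per-berry growth onset times (days), drawn uniformly.
#' @param rise_days 15-85% rise duration of the volume logistic (days).
#' @param amplitude relative volume amplitude ((V_max - V0)/V0).
#' @param shrivel_frac fraction of berries that shrivel after their peak.
#' @param shrivel_rate relative volume loss per day once shrivelling.
#' @param hue_start,hue_end raw hue before/after colour change (0-180
#'   scale); the transition runs circularly downward (green toward dark).
#' @param hue_lag_days lag of the hue-transition midpoint after the growth
#'   midpoint (days).
#' @param jitter_sd_px per-frame random-walk translation sd (px).
#' @param jitter_sd_deg per-frame random-walk rotation sd (degrees).
#' @param jitter_sd_scale per-frame random-walk log-scale sd.
#' @param events list of events, each `list(frame =, rotation = deg)` or
#'   `list(frame =, shuffle = TRUE)` (a non-affine re-arrangement of berry
#'   positions from that frame on).
#' @param noise_sd additive pixel noise of the renderer (0-1 scale).
#' @param seed integer seed; fully determines the simulation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_berries = 60, n_frames = 100, step_hours = 8,
                       image_size = c(612, 512), cluster_sd = 90,
                       radius_range = c(18, 26), aspect_range = c(1.0, 1.25),
                       onset_range = c(8, 18), rise_days = 18,
                       amplitude = 0.6, shrivel_frac = 0.3,
                       shrivel_rate = 0.004, hue_start = 60, hue_end = 150,
                       hue_lag_days = 4, jitter_sd_px = 1.5,
                       jitter_sd_deg = 0.5, jitter_sd_scale = 0.002,
                       events = list(), noise_sd = 0.02, seed = 1) {
  stopifnot(rise_days > 0, amplitude >= 0, n_berries >= 1, n_frames >= 1,
            step_hours > 0, radius_range[1] > 0)
  as.list(environment())
}

# plateau-logistic volume multiplier: 1 before onset, 1 + a after the rise.
# `onset` is the time of the 15% point, `rise` the 15-85% interval.
logistic_volume <- function(t, onset, rise, amplitude) {
  k <- 2 * log(0.85 / 0.15) / rise
  mid <- onset + rise / 2
  1 + amplitude / (1 + exp(-k * (t - mid)))
}

# circularly decreasing raw-hue transition on the 0-180 scale
logistic_hue <- function(t, mid, rise, hue_start, hue_end) {
  span <- (hue_start - hue_end) %% 180 # travelled downward
  k <- 2 * log(0.85 / 0.15) / rise
  (hue_start - span / (1 + exp(-k * (t - mid)))) %% 180
}

#' Simulate a ground-truthed berry time-lapse
#'
#' @param config a [sim_config()].
#' @return list of class `"bunch_sim"`: `frames` — data frame with one row
#'   per (frame, berry): `frame, time_days, berry_id, x_e, y_e, w_e, h_e,
#'   a_e, visibility, hue_raw, V_true`; `berries` — per-berry parameters
#'   (`berry_id, onset, rise_days, amplitude, hue_mid_time, depth`);
#'   `config` — the input configuration.
#' @export
simulate_bunch <- function(config = sim_config()) {
  cf <- config
  set.seed(cf$seed)
  nb <- cf$n_berries
  ctr <- c(cf$image_size[2] / 2, cf$image_size[1] / 2)
  pos <- cbind(stats::rnorm(nb, ctr[1], cf$cluster_sd),
               stats::rnorm(nb, ctr[2], cf$cluster_sd))
  # clamp inside the frame with a margin
  marg <- max(cf$radius_range) * 2.5
  pos[, 1] <- pmin(pmax(pos[, 1], marg), cf$image_size[2] - marg)
  pos[, 2] <- pmin(pmax(pos[, 2], marg), cf$image_size[1] - marg)
  r0 <- stats::runif(nb, cf$radius_range[1], cf$radius_range[2])
  aspect <- stats::runif(nb, cf$aspect_range[1], cf$aspect_range[2])
  ang0 <- stats::runif(nb, 0, 180)
  onset <- stats::runif(nb, cf$onset_range[1], cf$onset_range[2])
  depth <- sample.int(nb) # 1 = front
  shrivels <- stats::runif(nb) < cf$shrivel_frac
  hue_mid <- onset + cf$rise_days / 2 + cf$hue_lag_days

  times <- (seq_len(cf$n_frames) - 1) * cf$step_hours / 24
  # cumulative similarity jitter (rotation about the cluster centre)
  dth <- stats::rnorm(cf$n_frames, 0, cf$jitter_sd_deg) * pi / 180
  dsc <- exp(stats::rnorm(cf$n_frames, 0, cf$jitter_sd_scale))
  dtx <- stats::rnorm(cf$n_frames, 0, cf$jitter_sd_px)
  dty <- stats::rnorm(cf$n_frames, 0, cf$jitter_sd_px)
  dth[1] <- 0; dtx[1] <- 0; dty[1] <- 0; dsc[1] <- 1
  shuffle_at <- integer(0)
  for (ev in cf$events) {
    if (!is.null(ev$rotation)) dth[ev$frame] <- dth[ev$frame] + ev$rotation * pi / 180
    if (isTRUE(ev$shuffle)) shuffle_at <- c(shuffle_at, ev$frame)
  }
  theta <- cumsum(dth)
  scl <- cumprod(dsc)
  tx <- cumsum(dtx)
  ty <- cumsum(dty)

  # non-affine rearrangements: redraw positions, identities persist
  pos_list <- list(pos)
  for (s in seq_along(shuffle_at)) {
    np <- cbind(stats::rnorm(nb, ctr[1], cf$cluster_sd),
                stats::rnorm(nb, ctr[2], cf$cluster_sd))
    np[, 1] <- pmin(pmax(np[, 1], marg), cf$image_size[2] - marg)
    np[, 2] <- pmin(pmax(np[, 2], marg), cf$image_size[1] - marg)
    pos_list[[s + 1]] <- np
  }

  rows <- vector("list", cf$n_frames)
  for (f in seq_len(cf$n_frames)) {
    t <- times[f]
    vol <- logistic_volume(t, onset, cf$rise_days, cf$amplitude)
    peak_t <- onset + cf$rise_days
    shrink <- ifelse(shrivels & t > peak_t,
                     pmax(0.5, 1 - cf$shrivel_rate * (t - peak_t)), 1)
    vol <- vol * shrink
    lin <- vol^(1 / 3) # linear growth factor
    hue <- logistic_hue(t, hue_mid, cf$rise_days, cf$hue_start, cf$hue_end)
    p <- pos_list[[1 + sum(shuffle_at <= f)]]
    # frame similarity transform about the cluster centre
    co <- cos(theta[f]); si <- sin(theta[f])
    px <- p[, 1] - ctr[1]; py <- p[, 2] - ctr[2]
    qx <- scl[f] * (co * px - si * py) + ctr[1] + tx[f]
    qy <- scl[f] * (si * px + co * py) + ctr[2] + ty[f]
    w_e <- 2 * r0 * lin * scl[f]
    h_e <- w_e * aspect
    a_e <- (ang0 + theta[f] * 180 / pi) %% 180
    fr <- data.frame(frame = f, time_days = t, berry_id = seq_len(nb),
                     x_e = qx, y_e = qy, w_e = w_e, h_e = h_e, a_e = a_e,
                     hue_raw = hue,
                     V_true = sphere_volume((w_e / 2) * (h_e / 2) * pi))
    fr$visibility <- frame_visibility(fr, depth)
    rows[[f]] <- fr
  }
  frames <- do.call(rbind, rows)
  berries <- data.frame(berry_id = seq_len(nb), x0 = pos[, 1], y0 = pos[, 2],
                        r0 = r0, aspect = aspect, onset = onset,
                        rise_days = cf$rise_days, amplitude = cf$amplitude,
                        shrivels = shrivels, hue_mid_time = hue_mid,
                        depth = depth)
  structure(list(frames = frames, berries = berries, config = cf),
            class = "bunch_sim")
}

# visibility = fraction of a berry's boundary arc not covered by berries
# in front of it (smaller depth rank = nearer the camera)
frame_visibility <- function(fr, depth, n_arc = 120) {
  nb <- nrow(fr)
  vis <- numeric(nb)
  polys <- lapply(seq_len(nb), function(i)
    ellipse_polygon(fr[i, c("x_e", "y_e", "w_e", "h_e", "a_e")], n_arc))
  for (i in seq_len(nb)) {
    covered <- rep(FALSE, n_arc)
    front <- which(depth < depth[i])
    for (j in front) {
      e <- fr[j, c("x_e", "y_e", "w_e", "h_e", "a_e")]
      covered <- covered | in_ellipse(e, polys[[i]][, 1], polys[[i]][, 2])
      if (all(covered)) break
    }
    vis[i] <- mean(!covered)
  }
  vis
}

#' Render one simulated frame as an RGB raster
#'
#' Berries are painted back to front as filled ellipses in their frame's
#' raw hue (fixed saturation/value), over a plain background, with additive
#' Gaussian pixel noise. Rendering is deterministic given the simulation
#' seed and frame index.
#'
#' @param sim a [simulate_bunch()] result.
#' @param frame frame index.
#' @return array `[row, col, 3]` in `[0, 1]`.
#' @export
render_frame <- function(sim, frame) {
  cf <- sim$config
  fr <- sim$frames[sim$frames$frame == frame, , drop = FALSE]
  stopifnot(nrow(fr) > 0)
  h <- cf$image_size[1]; w <- cf$image_size[2]
  img <- array(0.12, dim = c(h, w, 3)) # dark neutral background
  ord <- order(-sim$berries$depth[match(fr$berry_id, sim$berries$berry_id)])
  for (i in ord) {
    m <- rasterize_ellipse(fr[i, c("x_e", "y_e", "w_e", "h_e", "a_e")], h, w)
    rgb <- grDevices::hsv(((fr$hue_raw[i] * 2) %% 360) / 360, 0.75, 0.65)
    col <- grDevices::col2rgb(rgb)[, 1] / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- col[ch]
      img[, , ch] <- plane
    }
  }
  set.seed(cf$seed * 1000003L %% .Machine$integer.max + frame)
  img <- img + array(stats::rnorm(h * w * 3, 0, cf$noise_sd), dim = dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Named scenario library
#'
#' Ready-made configurations covering the regimes the tracking and
#' kinetics stages must handle: a static bunch, nominal cumulative jitter,
#' an abrupt rigid rotation event, a non-affine rearrangement, dense
#' occlusion, and an asynchronous cohort whose onset spread is comparable
#' to the rise duration (the mean-berry bias demonstration).
#'
#' @param seed base seed applied to every scenario.
#' @return named list of [sim_config()] objects.
#' @export
scenario_library <- function(seed = 1) {
  list(
    static = sim_config(n_berries = 40, n_frames = 30, jitter_sd_px = 0,
                        jitter_sd_deg = 0, jitter_sd_scale = 0,
                        amplitude = 0, shrivel_frac = 0, seed = seed),
    nominal_jitter = sim_config(n_berries = 60, n_frames = 100, seed = seed),
    rigid_rotation_event = sim_config(
      n_berries = 45, n_frames = 40,
      events = list(list(frame = 20, rotation = 25)), seed = seed),
    nonaffine_break = sim_config(
      n_berries = 45, n_frames = 40,
      events = list(list(frame = 21, shuffle = TRUE)), seed = seed),
    dense_occlusion = sim_config(n_berries = 60, n_frames = 30,
                                 cluster_sd = 55, seed = seed),
    asynchronous_cohort = sim_config(
      n_berries = 50, n_frames = 180, cluster_sd = 120,
      onset_range = c(10, 28), rise_days = 18, shrivel_frac = 0,
      jitter_sd_px = 0.5, jitter_sd_deg = 0.2, jitter_sd_scale = 0,
      seed = seed)
  )
}

#' Visible detections of a simulated series
#'
#' The simulator-truth analogue of running the detection pipeline: keeps
#' berries with at least `min_visibility` visible contour per frame.
#'
#' @param sim a [simulate_bunch()] result.
#' @param min_visibility visibility cut.
#' @return list of per-frame data frames (columns as `sim$frames`).
#' @export
sim_detections <- function(sim, min_visibility = 0.5) {
  keep <- sim$frames[sim$frames$visibility >= min_visibility, , drop = FALSE]
  lapply(seq_len(sim$config$n_frames), function(f)
    keep[keep$frame == f, , drop = FALSE])
}

#' Measure a simulated series through the segmentation chain
#'
#' Runs the per-berry measurement path of the pipeline on simulator ground
#' truth without the detection stage: for every berry visible enough to be
#' measurable, the oracle segmentation mask is rasterized in vignette
#' coordinates (box geometry and `z` margin as in [crop_vignette()]), the
#' ellipse is re-fitted from the mask contour with [mask_to_ellipse()] and
#' the volume features are extracted. Identities are the ground-truth ones,
#' which isolates measurement + kinetics from tracking.
#'
#' @param sim a [simulate_bunch()] result.
#' @param min_visibility measurability cut on visible contour fraction.
#' @param config a [run_config()] (vignette geometry).
#' @return track data frame `label, frame, time_days, x_e, y_e, w_e, h_e,
#'   a_e, A_px2, V_px3, V_mL, H` (H from the simulated raw hue).
#' @export
sim_measured_tracks <- function(sim, min_visibility = 0.5,
                                config = run_config()) {
  keep <- sim$frames[sim$frames$visibility >= min_visibility, , drop = FALSE]
  size <- config$vignette_size
  n <- nrow(keep)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- keep[i, ]
    bb <- ellipse_to_bbox(g[, c("x_e", "y_e", "w_e", "h_e", "a_e")])
    crop_size <- max(bb$w_b, bb$h_b) / config$vignette_z
    tr <- list(crop_center = c(bb$x_b, bb$y_b), crop_size = crop_size,
               scale = size / crop_size)
    ev <- ellipse(size / 2, size / 2, g$w_e * tr$scale, g$h_e * tr$scale,
                  g$a_e)
    mask <- rasterize_ellipse(ev, size, size)
    e <- mask_to_ellipse(mask, tr)
    if (is.null(e)) next
    out[[i]] <- data.frame(label = g$berry_id, frame = g$frame,
                           time_days = g$time_days, x_e = e$x_e, y_e = e$y_e,
                           w_e = e$w_e, h_e = e$h_e, a_e = e$a_e,
                           H = centred_hue(g$hue_raw))
  }
  tracks <- do.call(rbind, out)
  tracks$A_px2 <- (tracks$w_e / 2) * (tracks$h_e / 2) * pi
  tracks$V_px3 <- sphere_volume(tracks$A_px2)
  tracks$V_mL <- volume_ml(tracks$V_px3)
  rownames(tracks) <- NULL
  tracks
}
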