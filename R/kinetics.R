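#' Single-berry ripening kinetics
#'
#' Turns labelled berry tracks into smoothed, normalised growth and colour
#' kinetics and scalar ripening descriptors. Volume series are smoothed
#' with an 8-day centred moving median; berries must be observed over at
#' least 90% of the experiment and the 10% with the noisiest volume signal
#' (highest MAPE between raw and smoothed volume) are excluded. Each
#' variable X (volume V or centred hue H) is expressed relative to its
#' early baseline `X_0` (median over the first 8 days) and scaled by
#' `X_max` (for V, the maximum of the smoothed values over the last 8
#' days; for H, the median over the last 8 days):
#' `X_r = (X - X_0)/X_0`, `X_s = (X - X_0)/(X_max - X_0)`.
#' Growth resumption and coloration start are the first upward crossings
#' of `V_s = 0.15` and `H_s = 0.15`; ripening duration
#' `RD = (t(V_s=0.85) - t(V_s=0.15)) / 0.7` and relative speed
#' `RS = dV_r / dt` over the same interval.
#'
#' @name kinetics
NULL

#' Centred moving median over a time window
#'
#' For each sample, the median of all values within `window/2` on either
#' side (window truncated at the series ends).
#'
#' @param times sample times (days), strictly increasing.
#' @param values sample values.
#' @param window full window width (days).
#' @return smoothed values, same length.
#' @export
moving_median <- function(times, values, window = 8) {
  stopifnot(length(times) == length(values), length(times) >= 1)
  half <- window / 2
  vapply(seq_along(times), function(i) {
    sel <- abs(times - times[i]) <= half
    stats::median(values[sel], na.rm = TRUE)
  }, numeric(1))
}

#' Assemble per-label berry series from a track table
#'
#' @param tracks data frame with columns `label, time_days, V_px3` (or
#'   `V`), optionally `H`; `label = -1` rows are ignored.
#' @param config a [run_config()].
#' @return list of berry series: each a list with `label, times, V, H,
#'   V_smooth, coverage, mape_fit`.
#' @export
berry_series <- function(tracks, config = run_config()) {
  vcol <- if ("V_px3" %in% names(tracks)) "V_px3" else "V"
  tracks <- tracks[!is.na(tracks$label) & tracks$label != -1, , drop = FALSE]
  all_frames <- length(unique(tracks$time_days))
  lapply(split(tracks, tracks$label), function(d) {
    d <- d[order(d$time_days), ]
    vs <- moving_median(d$time_days, d[[vcol]], config$smooth_window_days)
    list(label = d$label[1],
         times = d$time_days,
         V = d[[vcol]],
         H = if ("H" %in% names(d)) d$H else rep(NA_real_, nrow(d)),
         V_smooth = vs,
         coverage = nrow(d) / all_frames,
         mape_fit = mean(abs(d[[vcol]] - vs) / vs))
  })
}

#' Select analysable berries
#'
#' Keeps labels observed over at least `min_coverage` of the experiment
#' duration, then excludes the `mape_drop` fraction with the highest MAPE
#' between raw and smoothed volume (a fixed-size quantile exclusion, not a
#' threshold: noise-free cohorts still lose that fraction).
#'
#' @param series list from [berry_series()] (or a track data frame, which
#'   is converted first).
#' @param min_coverage minimum fraction of frames with an observation.
#' @param mape_drop fraction of the coverage-passing berries to drop.
#' @param config a [run_config()].
#' @return the retained subset of `series`.
#' @export
select_berries <- function(series, min_coverage = 0.90, mape_drop = 0.10,
                           config = run_config()) {
  if (is.data.frame(series)) series <- berry_series(series, config)
  cov_ok <- Filter(function(s) s$coverage >= min_coverage, series)
  n <- length(cov_ok)
  if (n == 0) return(cov_ok)
  n_drop <- floor(mape_drop * n)
  if (n_drop == 0) return(cov_ok)
  mape <- vapply(cov_ok, function(s) s$mape_fit, numeric(1))
  keep <- order(mape)[seq_len(n - n_drop)]
  cov_ok[sort(keep)]
}

#' Baseline-normalise a berry variable
#'
#' @param times,values the series (days, values); for V pass the smoothed
#'   series.
#' @param smooth_values smoothed values used for the late-window maximum
#'   (defaults to `values`).
#' @param variable `"V"` (late baseline = max of smoothed values over the
#'   last window) or `"H"` (median over the last window).
#' @param baseline_days early/late window width (days).
#' @return list `X_0, X_max, X_r, X_s, degenerate` (`degenerate = TRUE`
#'   when `X_max == X_0`, in which case `X_s` is `NA`).
#' @export
normalize_series <- function(times, values, smooth_values = values,
                             variable = c("V", "H"), baseline_days = 8) {
  variable <- match.arg(variable)
  stopifnot(diff(range(times)) > 2 * baseline_days)
  early <- times <= min(times) + baseline_days
  late <- times >= max(times) - baseline_days
  X0 <- stats::median(values[early], na.rm = TRUE)
  Xmax <- if (variable == "V") max(smooth_values[late], na.rm = TRUE)
          else stats::median(values[late], na.rm = TRUE)
  Xr <- (values - X0) / X0
  degen <- !is.finite(Xmax) || !is.finite(X0) || Xmax == X0
  Xs <- if (degen) rep(NA_real_, length(values)) else (values - X0) / (Xmax - X0)
  list(X_0 = X0, X_max = Xmax, X_r = Xr, X_s = Xs, degenerate = degen)
}

#' First upward crossing time of a level
#'
#' Linearly interpolated between samples; a series starting at or above
#' the level crosses at its first sample time.
#'
#' @param times,values the (scaled) series.
#' @param level crossing level.
#' @return time (days), or `NA` when the series never reaches the level.
#' @export
crossing_time <- function(times, values, level = 0.15) {
  ok <- is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(values) == 0) return(NA_real_)
  if (values[1] >= level) return(times[1])
  above <- which(values >= level)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  t0 <- times[i - 1]; t1 <- times[i]
  v0 <- values[i - 1]; v1 <- values[i]
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

#' Ripening descriptors of one berry
#'
#' @param s one berry series (list from [berry_series()]).
#' @param config a [run_config()].
#' @return one-row data frame `label, V_0, V_max, H_0, H_max, RD, RS,
#'   t_resume, t_color, max_rel_expansion, degenerate`.
#' @export
ripening_stats <- function(s, config = run_config()) {
  nv <- normalize_series(s$times, s$V_smooth, s$V_smooth, "V",
                         config$baseline_days)
  lo <- config$level_low; hi <- config$level_high
  t_lo <- crossing_time(s$times, nv$X_s, lo)
  t_hi <- crossing_time(s$times, nv$X_s, hi)
  rd <- rs <- NA_real_
  if (!nv$degenerate && !is.na(t_lo) && !is.na(t_hi)) {
    dt <- t_hi - t_lo
    rd <- dt / (hi - lo)
    vr_lo <- stats::approx(s$times, nv$X_r, t_lo)$y
    vr_hi <- stats::approx(s$times, nv$X_r, t_hi)$y
    rs <- (vr_hi - vr_lo) / dt
  }
  h_ok <- any(is.finite(s$H))
  t_color <- H0 <- Hmax <- NA_real_
  if (h_ok) {
    # daily-binned raw H for the colour crossing
    day <- floor(s$times)
    hd <- tapply(s$H, day, mean, na.rm = TRUE)
    ht <- as.numeric(names(hd)) + 0.5
    nh <- normalize_series(ht, as.numeric(hd), as.numeric(hd), "H",
                           config$baseline_days)
    H0 <- nh$X_0; Hmax <- nh$X_max
    if (!nh$degenerate) t_color <- crossing_time(ht, nh$X_s, lo)
  }
  data.frame(label = s$label, V_0 = nv$X_0, V_max = nv$X_max,
             H_0 = H0, H_max = Hmax, RD = rd, RS = rs,
             t_resume = t_lo, t_color = t_color,
             max_rel_expansion = (nv$X_max - nv$X_0) / nv$X_0,
             degenerate = nv$degenerate)
}

#' The daily-averaged "mean berry"
#'
#' Averages volume and centred hue across berries in calendar-day bins
#' (floor of time in days; days with no data are skipped) and runs the
#' result through the same smoothing/normalisation/descriptor pipeline.
#' With asynchronous berries its apparent ripening duration exceeds the
#' typical individual one: averaging adds the onset spread to the true
#' rise time.
#'
#' @param series list of berry series (at least 2).
#' @param config a [run_config()].
#' @return list `series` (the mean-berry series, same shape as one
#'   [berry_series()] element, label `"mean"`) and `stats`
#'   ([ripening_stats()] row).
#' @export
mean_berry <- function(series, config = run_config()) {
  stopifnot(length(series) >= 2)
  long <- do.call(rbind, lapply(series, function(s)
    data.frame(day = floor(s$times), V = s$V, H = s$H)))
  vd <- tapply(long$V, long$day, mean, na.rm = TRUE)
  hd <- tapply(long$H, long$day, mean, na.rm = TRUE)
  times <- as.numeric(names(vd)) + 0.5
  v <- as.numeric(vd)
  s <- list(label = "mean", times = times, V = v, H = as.numeric(hd),
            V_smooth = moving_median(times, v, config$smooth_window_days),
            coverage = 1, mape_fit = NA_real_)
  list(series = s, stats = ripening_stats(s, config))
}

#' Kinetics summary of a tracked series
#'
#' Runs selection, normalisation and descriptors for every retained berry
#' and the mean berry.
#'
#' @param tracks track data frame (`label, time_days, V_px3` and
#'   optionally `H`).
#' @param config a [run_config()].
#' @return list `summary` (per-berry data frame, mean berry last with
#'   label `"mean"`), `series` (retained [berry_series()] list),
#'   `kinetics` (long per-berry-per-time data frame with `V_r, V_s`).
#' @export
kinetics_summary <- function(tracks, config = run_config()) {
  series <- select_berries(berry_series(tracks, config),
                           config$min_coverage, config$mape_drop, config)
  if (length(series) == 0) {
    warning("no berry passes the coverage/MAPE filters")
    return(list(summary = data.frame(), series = list(), kinetics = data.frame()))
  }
  stats <- do.call(rbind, lapply(series, ripening_stats, config = config))
  if (any(stats$degenerate)) {
    message(sum(stats$degenerate), " berry(ies) with no dynamic range ",
            "excluded from RD/RS")
  }
  kin <- do.call(rbind, lapply(series, function(s) {
    nv <- normalize_series(s$times, s$V_smooth, s$V_smooth, "V",
                           config$baseline_days)
    data.frame(label = s$label, time_days = s$times, V_raw = s$V,
               V_smooth = s$V_smooth, V_r = nv$X_r, V_s = nv$X_s, H = s$H)
  }))
  if (length(series) >= 2) {
    mb <- mean_berry(series, config)
    mb$stats$label <- "mean"
    stats$label <- as.character(stats$label)
    stats <- rbind(stats, mb$stats)
  }
  rownames(stats) <- NULL
  list(summary = stats, series = series, kinetics = kin)
}
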