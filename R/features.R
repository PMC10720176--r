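#' Per-berry colour and size features
#'
#' Colour is summarised as the circular mean hue of the pixels safely
#' inside a berry's ellipse — at least `dp = max(3, w_e/4)` px away from
#' its edge (computed on the rasterized mask with a Euclidean distance
#' transform) and not shared with any other ellipse of the frame. Hue is
#' expressed on the half-circle 0-180 degree scale throughout (standard
#' 0-360 hue divided by two). Size is the projected ellipse area and the
#' volume of the sphere with the same cross-section area.
#'
#' @name features
NULL

#' Pixels usable for a berry's colour measurement
#'
#' @param e the berry's [ellipse()].
#' @param others list (or data frame) of the frame's other ellipses.
#' @param image_shape `c(nrow, ncol)` of the image.
#' @param dp_min,dp_frac edge margin rule `dp = max(dp_min, w_e/dp_frac)`.
#' @return data frame `row, col, x, y` of retained pixels (possibly empty).
#' @export
berry_pixel_set <- function(e, others = list(), image_shape,
                            dp_min = 3, dp_frac = 4) {
  e <- as_ellipse(e)
  dp <- max(dp_min, e$w_e / dp_frac)
  b <- ellipse_to_bbox(e)
  # window with a 1 px background rim so the distance transform sees the edge
  r0 <- max(1L, floor(b$y_b - b$h_b / 2)); r1 <- min(image_shape[1], ceiling(b$y_b + b$h_b / 2) + 1L)
  c0 <- max(1L, floor(b$x_b - b$w_b / 2)); c1 <- min(image_shape[2], ceiling(b$x_b + b$w_b / 2) + 1L)
  if (r0 > r1 || c0 > c1) return(data.frame(row = integer(), col = integer(), x = numeric(), y = numeric()))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(y = rr - 0.5, x = cc - 0.5)
  inside <- matrix(in_ellipse(e, g$x, g$y, strict = TRUE), nrow = length(rr))
  if (!any(inside)) return(data.frame(row = integer(), col = integer(), x = numeric(), y = numeric()))
  dmap <- EBImage::distmap(inside * 1L)
  dmap <- matrix(as.numeric(dmap), length(rr), length(cc))
  keep <- inside & dmap >= dp
  if (length(others)) {
    if (is.data.frame(others)) others <- split(others, seq_len(nrow(others)))
    for (o in others) {
      if (!any(keep)) break
      oin <- matrix(in_ellipse(as_ellipse(o), g$x, g$y, strict = TRUE),
                    nrow = length(rr))
      keep <- keep & !oin
    }
  }
  idx <- which(keep, arr.ind = TRUE)
  data.frame(row = rr[idx[, 1]], col = cc[idx[, 2]],
             x = cc[idx[, 2]] - 0.5, y = rr[idx[, 1]] - 0.5)
}

#' Circular mean of hue values on the 0-180 degree scale
#'
#' @param hues numeric vector of hue values (0-180 half-circle scale).
#' @return the circular mean in `[0, 180)`, or `NA` (with a warning) when
#'   the input is empty or the resultant vector length is ~0 (undefined
#'   mean direction).
#' @export
circular_mean_hue <- function(hues) {
  if (length(hues) == 0) {
    warning("empty hue set; mean hue undefined")
    return(NA_real_)
  }
  ang <- hues * 2 * pi / 180 # 180-degree period mapped onto the full circle
  sx <- mean(cos(ang)); sy <- mean(sin(ang))
  if (sqrt(sx^2 + sy^2) < 1e-9) {
    warning("resultant vector ~0; mean hue undefined")
    return(NA_real_)
  }
  (atan2(sy, sx) * 180 / (2 * pi)) %% 180
}

#' Centred berry hue
#'
#' `H = (180 - h_raw - h_50) mod 180`, with the modulo mapping negative
#' arguments into `[0, 180)`. `h_50` is the mean raw hue of berries halfway
#' through their colour change, so H is anchored to that reference point.
#'
#' @param h_raw raw hue (0-180 scale).
#' @param h_50 reference hue (degrees).
#' @return centred hue in `[0, 180)`.
#' @export
centred_hue <- function(h_raw, h_50 = 100) {
  (180 - h_raw - h_50) %% 180
}

#' Projected area of a berry ellipse
#'
#' `A = (w_e/2) * (h_e/2) * pi` in px^2.
#'
#' @param e an [ellipse()] (or anything with `w_e`, `h_e`).
#' @return area (px^2).
#' @export
projected_area <- function(e) {
  e <- as.list(e)
  (e$w_e / 2) * (e$h_e / 2) * pi
}

#' Sphere-equivalent berry volume
#'
#' The volume of the sphere whose cross-section (great-circle) area equals
#' the projected area `A`: a sphere of radius `r = sqrt(A/pi)`, hence
#' `V = (4*pi/3) * (A/pi)^(3/2)` in px^3. `printed_form = TRUE` switches to
#' the dimensionally inconsistent variant `(4*pi/3) * (A/pi)^(1/3)` kept
#' for compatibility with the formula as sometimes printed.
#'
#' @param A projected area (px^2), `> 0`.
#' @param printed_form use the cube-root variant.
#' @return volume (px^3).
#' @export
sphere_volume <- function(A, printed_form = FALSE) {
  stopifnot(all(A > 0))
  ex <- if (printed_form) 1 / 3 else 3 / 2
  (4 * pi / 3) * (A / pi)^ex
}

#' Convert a pixel volume to millilitres
#'
#' @param V_px3 volume in px^3.
#' @param ml_per_px3 calibration factor (mL per px^3).
#' @return volume in mL.
#' @export
volume_ml <- function(V_px3, ml_per_px3 = 3.94e-6) {
  V_px3 * ml_per_px3
}

#' Extract colour and size features for every berry of a frame
#'
#' Appends `h_raw, H, A_px2, V_px3, V_mL` to a frame's detections. Berries
#' whose usable pixel set is empty get `NA` hue (with a warning naming the
#' berry); area and volume are always defined.
#'
#' @param image array `[row, col, 3]` or `NULL` to skip colour features.
#' @param detections data frame with ellipse columns (`x_e ... a_e`).
#' @param config a [run_config()].
#' @return `detections` with feature columns appended.
#' @export
extract_features <- function(image, detections, config = run_config()) {
  n <- nrow(detections)
  detections$A_px2 <- (detections$w_e / 2) * (detections$h_e / 2) * pi
  detections$V_px3 <- sphere_volume(detections$A_px2)
  detections$V_mL <- volume_ml(detections$V_px3, config$ml_per_px3)
  detections$h_raw <- NA_real_
  if (!is.null(image) && n > 0) {
    shape <- dim(image)[1:2]
    hue_mat <- NULL
    for (i in seq_len(n)) {
      px <- berry_pixel_set(detections[i, ], detections[-i, , drop = FALSE],
                            shape, config$dp_min, config$dp_frac)
      if (nrow(px) == 0) {
        warning(sprintf("berry %d: no usable pixels for hue; hue undefined", i))
        next
      }
      idx <- cbind(px$row, px$col)
      hsv <- grDevices::rgb2hsv(rbind(image[cbind(idx, 1)],
                                      image[cbind(idx, 2)],
                                      image[cbind(idx, 3)]) * 255,
                                maxColorValue = 255)
      detections$h_raw[i] <- suppressWarnings(circular_mean_hue(hsv[1, ] * 180))
    }
  }
  detections$H <- ifelse(is.na(detections$h_raw), NA_real_,
                         centred_hue(detections$h_raw, config$h_50))
  detections
}
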