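#' Detection and segmentation plumbing
#'
#' The neural predictors themselves are pluggable: a predictor is a list
#' with two functions, `detect(tile, offset)` returning a box data frame
#' (columns `x_b, y_b, w_b, h_b, score`, tile coordinates) for one image
#' tile, and `segment(vignette, transform)` returning a 128 x 128 binary
#' mask for one berry vignette. [oracle_predictor()] builds a
#' ground-truth-driven predictor for synthetic renders; trained models plug
#' in through the same seam.
#'
#' @name detect-segment
NULL

empty_boxes <- function() {
  data.frame(x_b = numeric(), y_b = numeric(), w_b = numeric(),
             h_b = numeric(), score = numeric())
}

#' Plan detection tiles over an image
#'
#' Covers the full pixel range with square tiles whose top-left offsets are
#' evenly spaced with at most `max_spacing` px between consecutive offsets
#' along each axis; offsets always include 0 and `dim - tile_size`. Images
#' smaller than one tile are handled by a single tile with zero padding.
#'
#' @param image_height,image_width image dimensions (px).
#' @param tile_size tile side (px); detector input size.
#' @param max_spacing maximum offset spacing (px).
#' @return list with `offsets` (data frame `col`, `row` of top-left
#'   corners) and `tile_size`.
#' @export
plan_tiles <- function(image_height, image_width, tile_size = 416,
                       max_spacing = 270) {
  stopifnot(image_height > 0, image_width > 0)
  axis_offsets <- function(dim) {
    if (dim <= tile_size) return(0)
    n <- ceiling((dim - tile_size) / max_spacing) + 1
    round(seq(0, dim - tile_size, length.out = n))
  }
  off <- expand.grid(col = axis_offsets(image_width),
                     row = axis_offsets(image_height))
  list(offsets = off, tile_size = tile_size)
}

#' Non-maximum suppression of detection boxes
#'
#' Greedy by descending score; a box is suppressed when its IoU with an
#' already kept box exceeds `iou_max`.
#'
#' @param boxes data frame with columns `x_b, y_b, w_b, h_b, score`.
#' @param iou_max suppression threshold on box IoU.
#' @return the surviving rows, ordered by descending score.
#' @export
nms <- function(boxes, iou_max = 0.70) {
  if (is.null(boxes) || nrow(boxes) == 0) return(empty_boxes())
  ord <- order(-boxes$score, seq_len(nrow(boxes)))
  b <- boxes[ord, , drop = FALSE]
  x0 <- b$x_b - b$w_b / 2; x1 <- b$x_b + b$w_b / 2
  y0 <- b$y_b - b$h_b / 2; y1 <- b$y_b + b$h_b / 2
  area <- b$w_b * b$h_b
  keep <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    ks <- which(keep)
    if (length(ks)) {
      ix <- pmax(0, pmin(x1[i], x1[ks]) - pmax(x0[i], x0[ks]))
      iy <- pmax(0, pmin(y1[i], y1[ks]) - pmax(y0[i], y0[ks]))
      inter <- ix * iy
      iou <- inter / (area[i] + area[ks] - inter)
      if (any(iou > iou_max)) next
    }
    keep[i] <- TRUE
  }
  b[keep, , drop = FALSE]
}

#' Filter detections by confidence score
#'
#' @param boxes box data frame.
#' @param s confidence threshold; boxes with `score >= s` are kept.
#' @return the surviving rows.
#' @export
filter_confidence <- function(boxes, s = 0.89) {
  if (is.null(boxes) || nrow(boxes) == 0) return(empty_boxes())
  boxes[boxes$score >= s, , drop = FALSE]
}

#' Crop and resize a berry vignette
#'
#' Crops a square of side `max(w_b, h_b) / z` centred on the box centre,
#' zero-padding any out-of-frame area, and resizes it to
#' `size x size` px by bilinear interpolation. The returned transform makes
#' the vignette-to-image coordinate map exactly invertible.
#'
#' @param image array `[row, col, 3]`.
#' @param box one-row box data frame or [box()].
#' @param z vignette margin constant; the berry occupies a fraction `z` of
#'   the vignette side.
#' @param size output side (px).
#' @return list `vignette` (array `[size, size, 3]`) and `transform` (list
#'   `crop_center`, `crop_size`, `scale`).
#' @export
crop_vignette <- function(image, box, z = 0.75, size = 128) {
  box <- as.list(box)
  crop_size <- max(box$w_b, box$h_b) / z
  stopifnot(crop_size > 0)
  scale <- size / crop_size
  tr <- list(crop_center = c(box$x_b, box$y_b), crop_size = crop_size,
             scale = scale)
  uv <- seq_len(size) - 0.5
  g <- expand.grid(v = uv, u = uv) # row-major fill: v fastest
  xy <- vignette_to_image(tr, g$u, g$v, size = size)
  vig <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    vig[, , ch] <- matrix(bilinear_sample(image[, , ch], xy[, 1], xy[, 2]),
                          nrow = size)
  }
  list(vignette = vig, transform = tr)
}

#' Map vignette coordinates to image coordinates (and back)
#'
#' @param transform a `VignetteTransform` from [crop_vignette()].
#' @param u,v (or `x,y`) continuous coordinates.
#' @param size vignette side (px).
#' @return two-column matrix of mapped coordinates.
#' @export
vignette_to_image <- function(transform, u, v, size = 128) {
  cbind(x = transform$crop_center[1] + (u - size / 2) / transform$scale,
        y = transform$crop_center[2] + (v - size / 2) / transform$scale)
}

#' @rdname vignette_to_image
#' @param x,y image coordinates.
#' @export
image_to_vignette <- function(transform, x, y, size = 128) {
  cbind(u = (x - transform$crop_center[1]) * transform$scale + size / 2,
        v = (y - transform$crop_center[2]) * transform$scale + size / 2)
}

#' Fit an ellipse to a segmentation mask and map it to image coordinates
#'
#' Extracts the sub-pixel contour (pixel-edge midpoints) of the largest
#' foreground component, fits an ellipse to it and back-projects the
#' parameters through the vignette transform.
#'
#' @param mask binary `size x size` matrix.
#' @param transform the `VignetteTransform` of the vignette.
#' @param min_px minimum component size (px) for a usable mask.
#' @return An [ellipse()] in image coordinates with attribute
#'   `"border_touch"` set to `TRUE` when the component touches the vignette
#'   frame, or `NULL` when the mask is empty/too small or the fit fails.
#' @export
mask_to_ellipse <- function(mask, transform, min_px = 20) {
  size <- nrow(mask)
  comp <- largest_component(mask > 0)
  if (is.null(comp) || sum(comp) < min_px) return(NULL)
  pts <- mask_contour_points(comp)
  ev <- tryCatch(fit_ellipse(pts),
                 berrytrack_fit_failure = function(c) NULL)
  if (is.null(ev)) return(NULL)
  ctr <- vignette_to_image(transform, ev$x_e, ev$y_e, size = size)
  e <- ellipse(ctr[1], ctr[2], ev$w_e / transform$scale,
               ev$h_e / transform$scale, ev$a_e)
  attr(e, "border_touch") <- any(comp[1, ]) || any(comp[size, ]) ||
    any(comp[, 1]) || any(comp[, size])
  e
}

#' Run the detection + segmentation pipeline on one frame
#'
#' Tiles the image, runs the plug-in detector per tile (keeping only boxes
#' entirely inside their tile; the tile overlap recovers boxes clipped by a
#' tile edge), merges to image coordinates, applies non-maximum suppression
#' and the confidence filter, then segments each surviving box and fits the
#' berry ellipse.
#'
#' @param image array `[row, col, 3]`.
#' @param predictor a predictor list (see [oracle_predictor()]).
#' @param config a [run_config()]; supplies tile, NMS, confidence and
#'   vignette parameters.
#' @return data frame with one row per measurable berry: columns
#'   `x_e, y_e, w_e, h_e, a_e, score`.
#' @export
run_frame <- function(image, predictor, config = run_config()) {
  ts <- config$tile_size
  h <- dim(image)[1]; w <- dim(image)[2]
  pad_h <- max(h, ts); pad_w <- max(w, ts)
  if (pad_h > h || pad_w > w) {
    padded <- array(0, dim = c(pad_h, pad_w, 3))
    padded[seq_len(h), seq_len(w), ] <- image
    image <- padded
  }
  plan <- plan_tiles(pad_h, pad_w, ts, config$tile_spacing)
  pooled <- list()
  for (i in seq_len(nrow(plan$offsets))) {
    oc <- plan$offsets$col[i]; orow <- plan$offsets$row[i]
    tile <- image[orow + seq_len(ts), oc + seq_len(ts), , drop = FALSE]
    bx <- predictor$detect(tile, c(oc, orow))
    if (is.null(bx) || nrow(bx) == 0) next
    inside <- bx$x_b - bx$w_b / 2 >= 0 & bx$x_b + bx$w_b / 2 <= ts &
              bx$y_b - bx$h_b / 2 >= 0 & bx$y_b + bx$h_b / 2 <= ts
    bx <- bx[inside, , drop = FALSE]
    if (nrow(bx) == 0) next
    bx$x_b <- bx$x_b + oc
    bx$y_b <- bx$y_b + orow
    pooled[[length(pooled) + 1]] <- bx
  }
  boxes <- if (length(pooled)) do.call(rbind, pooled) else empty_boxes()
  boxes <- filter_confidence(nms(boxes, config$nms_iou), config$conf_threshold)
  out <- list()
  for (i in seq_len(nrow(boxes))) {
    cv <- crop_vignette(image, boxes[i, ], z = config$vignette_z,
                        size = config$vignette_size)
    mask <- predictor$segment(cv$vignette, cv$transform)
    e <- mask_to_ellipse(mask, cv$transform)
    if (is.null(e)) {
      warning(sprintf("berry %d: empty mask or ellipse fit failure; skipped", i))
      next
    }
    out[[length(out) + 1]] <-
      data.frame(x_e = e$x_e, y_e = e$y_e, w_e = e$w_e, h_e = e$h_e,
                 a_e = e$a_e, score = boxes$score[i])
  }
  if (length(out) == 0) {
    return(data.frame(x_e = numeric(), y_e = numeric(), w_e = numeric(),
                      h_e = numeric(), a_e = numeric(), score = numeric()))
  }
  do.call(rbind, out)
}

#' Ground-truth oracle predictor for synthetic renders
#'
#' Emulates the trained detector/segmenter on simulator output: `detect`
#' returns the enclosing boxes of berries whose visible contour fraction is
#' at least `min_visibility` (score = visibility), and `segment` returns
#' the rasterized complete ground-truth ellipse of the berry the vignette
#' is centred on — the full shape, not the visible crescent, mirroring the
#' occlusion-inference behaviour the segmenter is trained for.
#'
#' @param gt_frame one frame of simulator ground truth: data frame with
#'   columns `berry_id, x_e, y_e, w_e, h_e, a_e, visibility`.
#' @param min_visibility detection visibility threshold.
#' @return a predictor list with `detect` and `segment`.
#' @export
oracle_predictor <- function(gt_frame, min_visibility = 0.5) {
  vis <- gt_frame[gt_frame$visibility >= min_visibility, , drop = FALSE]
  detect <- function(tile, offset = c(0, 0)) {
    if (nrow(vis) == 0) return(empty_boxes())
    bl <- lapply(seq_len(nrow(vis)), function(i) {
      b <- ellipse_to_bbox(vis[i, c("x_e", "y_e", "w_e", "h_e", "a_e")])
      data.frame(x_b = b$x_b - offset[1], y_b = b$y_b - offset[2],
                 w_b = b$w_b, h_b = b$h_b, score = vis$visibility[i])
    })
    do.call(rbind, bl)
  }
  segment <- function(vignette, transform) {
    size <- dim(vignette)[1]
    if (nrow(vis) == 0) return(matrix(FALSE, size, size))
    d2 <- (vis$x_e - transform$crop_center[1])^2 +
          (vis$y_e - transform$crop_center[2])^2
    g <- vis[which.min(d2), ]
    uv <- image_to_vignette(transform, g$x_e, g$y_e, size = size)
    ev <- ellipse(uv[1], uv[2], g$w_e * transform$scale,
                  g$h_e * transform$scale, g$a_e)
    rasterize_ellipse(ev, size, size)
  }
  list(detect = detect, segment = segment)
}
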