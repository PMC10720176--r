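# Detection/segmentation plumbing around the pluggable predictors.

test_that("plan_tiles covers the full image with bounded spacing", {
  p <- plan_tiles(416, 416)
  expect_equal(nrow(p$offsets), 1)
  expect_equal(unlist(p$offsets[1, ]), c(col = 0, row = 0))
  # undersized image: single (padded) tile
  p <- plan_tiles(400, 400)
  expect_equal(nrow(p$offsets), 1)

  p <- plan_tiles(2048, 2448)
  for (ax in c("col", "row")) {
    off <- sort(unique(p$offsets[[ax]]))
    expect_equal(off[1], 0)
    expect_true(all(diff(off) <= 270))
  }
  expect_equal(max(p$offsets$col), 2448 - 416)
  expect_equal(max(p$offsets$row), 2048 - 416)
  # boolean coverage oracle
  covered_c <- rep(FALSE, 2448); covered_r <- rep(FALSE, 2048)
  for (i in seq_len(nrow(p$offsets))) {
    covered_c[p$offsets$col[i] + 1:416] <- TRUE
    covered_r[p$offsets$row[i] + 1:416] <- TRUE
  }
  expect_true(all(covered_c) && all(covered_r))
  expect_error(plan_tiles(0, 100))
})

test_that("nms keeps the best box of an overlapping pair, all survivors compatible", {
  two <- data.frame(x_b = c(10, 10), y_b = c(10, 10), w_b = 8, h_b = 8,
                    score = c(0.9, 0.8))
  expect_equal(nms(two)$score, 0.9)
  apart <- data.frame(x_b = c(0, 100), y_b = 0, w_b = 8, h_b = 8,
                      score = c(0.9, 0.8))
  expect_equal(nrow(nms(apart)), 2)
  # A contains B (IoU > 0.7), C far away
  abc <- data.frame(x_b = c(10, 10, 200), y_b = 10, w_b = c(10, 9, 10),
                    h_b = c(10, 9, 10), score = c(0.9, 0.8, 0.5))
  out <- nms(abc)
  expect_setequal(out$score, c(0.9, 0.5))
  expect_equal(nrow(nms(data.frame())), 0)

  # property: no surviving pair exceeds the threshold, and every removed
  # box conflicts with a kept higher-scoring one
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    b <- data.frame(x_b = runif(n, 0, 60), y_b = runif(n, 0, 60),
                    w_b = runif(n, 5, 25), h_b = runif(n, 5, 25),
                    score = runif(n))
    out <- nms(b)
    if (nrow(out) > 1) {
      for (i in 1:(nrow(out) - 1)) {
        for (j in (i + 1):nrow(out)) {
          expect_lte(berrytrack:::box_iou(out[i, ], out[j, ]), 0.70)
        }
      }
    }
    removed <- b[!rownames(b) %in% rownames(out), , drop = FALSE]
    for (i in seq_len(nrow(removed))) {
      conflicts <- vapply(seq_len(nrow(out)), function(j)
        berrytrack:::box_iou(removed[i, ], out[j, ]) > 0.70 &&
          out$score[j] >= removed$score[i], logical(1))
      expect_true(any(conflicts))
    }
  }
})

test_that("confidence filter keeps the boundary score", {
  b <- data.frame(x_b = 1:3, y_b = 1, w_b = 5, h_b = 5,
                  score = c(0.95, 0.89, 0.50))
  expect_equal(filter_confidence(b)$score, c(0.95, 0.89))
  expect_equal(nrow(filter_confidence(data.frame())), 0)
  all1 <- data.frame(x_b = 1:3, y_b = 1, w_b = 5, h_b = 5, score = 1)
  expect_equal(nrow(filter_confidence(all1)), 3)
})

test_that("vignette crop geometry and round-trip are exact", {
  img <- array(runif(200 * 200 * 3), dim = c(200, 200, 3))
  cv <- crop_vignette(img, data.frame(x_b = 100, y_b = 100, w_b = 96, h_b = 96))
  expect_equal(cv$transform$crop_size, 128) # 96/0.75
  expect_equal(cv$transform$scale, 1)
  cv <- crop_vignette(img, data.frame(x_b = 100, y_b = 100, w_b = 48, h_b = 40))
  expect_equal(cv$transform$crop_size, 64)
  expect_equal(cv$transform$scale, 2)
  # border box: transform still exactly invertible
  cv <- crop_vignette(img, data.frame(x_b = 5, y_b = 195, w_b = 60, h_b = 48))
  set.seed(22)
  pts <- cbind(runif(20, 0, 128), runif(20, 0, 128))
  xy <- vignette_to_image(cv$transform, pts[, 1], pts[, 2])
  uv <- image_to_vignette(cv$transform, xy[, 1], xy[, 2])
  expect_lt(max(abs(uv - pts)), 0.5)
})

test_that("mask_to_ellipse recovers a rasterized ellipse and flags failures", {
  e <- ellipse(40, 64, 50, 80, 0)
  mask <- rasterize_ellipse(e, 128, 128)
  ident <- list(crop_center = c(64, 64), crop_size = 128, scale = 1)
  f <- mask_to_ellipse(mask, ident)
  expect_lt(abs(f$x_e - 40), 1)
  expect_lt(abs(f$y_e - 64), 1)
  expect_lt(abs(f$w_e - 50), 1)
  expect_lt(abs(f$h_e - 80), 1)
  ad <- abs(f$a_e - 0); expect_lt(min(ad, 180 - ad), 2)

  expect_null(mask_to_ellipse(matrix(FALSE, 128, 128), ident))
  full <- mask_to_ellipse(matrix(TRUE, 128, 128), ident)
  expect_true(attr(full, "border_touch"))
})

test_that("run_frame measures synthetic berries end to end", {
  cfg <- sim_config(n_berries = 12, n_frames = 1, image_size = c(416, 416),
                    cluster_sd = 110, radius_range = c(12, 16),
                    jitter_sd_px = 0, jitter_sd_deg = 0, jitter_sd_scale = 0,
                    seed = 5)
  sim <- simulate_bunch(cfg)
  gt <- sim$frames
  rc <- run_config(conf_threshold = 0.5)
  blank <- array(0.1, dim = c(416, 416, 3))
  expect_equal(nrow(run_frame(blank, oracle_predictor(gt[0, ]), rc)), 0)

  img <- render_frame(sim, 1)
  det <- suppressWarnings(run_frame(img, oracle_predictor(gt), rc))
  vis <- gt[gt$visibility >= 0.5, ]
  expect_equal(nrow(det), nrow(vis))
  m <- match_instances(det, vis)
  expect_equal(m$FN, 0)
  for (k in seq_len(nrow(m$pairs))) {
    expect_gte(ellipse_iou(det[m$pairs[k, 1], ], vis[m$pairs[k, 2], ]), 0.9)
  }
  # berries below 50% visibility are absent from the output
  hidden <- gt[gt$visibility < 0.5, ]
  if (nrow(hidden)) {
    for (k in seq_len(nrow(hidden))) {
      ious <- vapply(seq_len(nrow(det)), function(i)
        ellipse_iou(det[i, ], hidden[k, ]), numeric(1))
      expect_true(all(ious < 0.9))
    }
  }
})

test_that("pipeline output boxes are NMS-compatible on a dense render", {
  cfg <- sim_config(n_berries = 20, n_frames = 1, image_size = c(416, 416),
                    cluster_sd = 60, radius_range = c(12, 16),
                    jitter_sd_px = 0, jitter_sd_deg = 0, jitter_sd_scale = 0,
                    seed = 6)
  sim <- simulate_bunch(cfg)
  img <- render_frame(sim, 1)
  det <- suppressWarnings(
    run_frame(img, oracle_predictor(sim$frames), run_config(conf_threshold = 0.5)))
  if (nrow(det) > 1) {
    for (i in 1:(nrow(det) - 1)) {
      bi <- ellipse_to_bbox(det[i, c("x_e", "y_e", "w_e", "h_e", "a_e")])
      for (j in (i + 1):nrow(det)) {
        bj <- ellipse_to_bbox(det[j, c("x_e", "y_e", "w_e", "h_e", "a_e")])
        expect_lte(berrytrack:::box_iou(bi, bj), 0.70 + 1e-9)
      }
    }
  }
})
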