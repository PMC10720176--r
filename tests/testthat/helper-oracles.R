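# Independent brute-force oracles used across tests.

# random ellipse with well-conditioned axes
random_ellipse <- function(x_range = c(-50, 50), w_range = c(4, 30),
                           h_range = c(4, 60)) {
  ellipse(runif(1, x_range[1], x_range[2]), runif(1, x_range[1], x_range[2]),
          runif(1, w_range[1], w_range[2]), runif(1, h_range[1], h_range[2]),
          runif(1, 0, 180))
}

# parameter distance between two ellipses, handling the near-circle angle
# ambiguity: angle only compared when meaningfully elongated, weighted by
# the arc displacement it causes
ellipse_param_err <- function(fit, truth) {
  err <- max(abs(fit$x_e - truth$x_e), abs(fit$y_e - truth$y_e),
             abs(fit$w_e - truth$w_e) / truth$w_e,
             abs(fit$h_e - truth$h_e) / truth$h_e)
  if (truth$h_e / truth$w_e > 1.05) {
    ad <- abs(fit$a_e - truth$a_e)
    err <- max(err, min(ad, 180 - ad) * pi / 180)
  }
  err
}

# pixel-membership IoU oracle on a fine grid covering both ellipses
pixel_iou_oracle <- function(e1, e2, step = 0.25) {
  b1 <- ellipse_to_bbox(e1); b2 <- ellipse_to_bbox(e2)
  x0 <- min(b1$x_b - b1$w_b / 2, b2$x_b - b2$w_b / 2)
  x1 <- max(b1$x_b + b1$w_b / 2, b2$x_b + b2$w_b / 2)
  y0 <- min(b1$y_b - b1$h_b / 2, b2$y_b - b2$h_b / 2)
  y1 <- max(b1$y_b + b1$h_b / 2, b2$y_b + b2$h_b / 2)
  g <- expand.grid(x = seq(x0, x1, by = step), y = seq(y0, y1, by = step))
  in1 <- in_ellipse(e1, g$x, g$y)
  in2 <- in_ellipse(e2, g$x, g$y)
  if (!any(in1 | in2)) return(0)
  sum(in1 & in2) / sum(in1 | in2)
}

# greedy matching re-derived step by step: repeatedly scan the full
# distance table for the smallest admissible pair (ties: lowest a, then b),
# consume both points. Independent of the sorted-candidate implementation.
greedy_match_oracle <- function(a, b, delta = 16) {
  out <- matrix(integer(), ncol = 2)
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  free_a <- rep(TRUE, nrow(a)); free_b <- rep(TRUE, nrow(b))
  repeat {
    best <- NULL; best_d <- Inf
    for (i in which(free_a)) {
      for (j in which(free_b)) {
        if (d[i, j] <= delta && d[i, j] < best_d) {
          best <- c(i, j); best_d <- d[i, j]
        }
      }
    }
    if (is.null(best)) break
    out <- rbind(out, best)
    free_a[best[1]] <- FALSE; free_b[best[2]] <- FALSE
  }
  dimnames(out) <- list(NULL, c("a", "b"))
  out
}

# maximum-cardinality one-to-one matching over pairs with IoU > iou_min,
# by exhaustive recursion (small instances only)
optimal_match_count <- function(iou, iou_min = 0.5) {
  np <- nrow(iou); nt <- ncol(iou)
  if (np == 0 || nt == 0) return(0L)
  best <- 0L
  rec <- function(i, used_t, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) {
      best <<- max(best, count)
      return()
    }
    rec(i + 1, used_t, count) # skip prediction i
    for (j in seq_len(nt)) {
      if (!used_t[j] && iou[i, j] > iou_min) {
        used_t[j] <- TRUE
        rec(i + 1, used_t, count + 1L)
        used_t[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nt), 0L)
  best
}

# small simulated series tracked against ground truth
scored_tracking <- function(cfg, use_registration = TRUE, use_tree = TRUE,
                            config = run_config()) {
  sim <- simulate_bunch(cfg)
  det <- sim_detections(sim)
  tr <- track_series(det, use_registration = use_registration,
                     use_tree = use_tree, config = config)
  truth <- unlist(lapply(det, function(f) f$berry_id))
  list(score = tracking_score(tr$table, truth), result = tr, sim = sim)
}
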