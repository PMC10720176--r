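# Greedy matching, CPD registration, set distances, matching tree and
# label propagation.

test_that("greedy matching follows the closest-first one-to-one rule", {
  a <- rbind(c(0, 0), c(3, 4))
  expect_equal(greedy_match(a, a)[, "b"], c(1, 2))
  # 20 px apart: above delta, no pair
  expect_equal(nrow(greedy_match(rbind(c(0, 0)), rbind(c(20, 0)))), 0)
  # consumed point blocks the second match
  m <- greedy_match(rbind(c(0, 0), c(10, 0)), rbind(c(1, 0)))
  expect_equal(unname(m[1, ]), c(1, 1))
  expect_equal(nrow(m), 1)
  expect_equal(nrow(greedy_match(matrix(numeric(), 0, 2), a)), 0)
})

test_that("greedy matching agrees with its step-by-step oracle", {
  set.seed(41)
  for (rep in 1:80) {
    na <- sample(0:8, 1); nb <- sample(0:8, 1)
    a <- matrix(runif(2 * na, 0, 30), ncol = 2)
    b <- matrix(runif(2 * nb, 0, 30), ncol = 2)
    expect_equal(unname(greedy_match(a, b)),
                 unname(greedy_match_oracle(a, b)))
  }
})

test_that("affine CPD recovers known transforms", {
  set.seed(42)
  X <- matrix(runif(100, 0, 500), 50, 2)
  r0 <- register_affine(X, X)
  expect_lt(symmetric_distance_D(X, r0$points), 1e-6)

  th <- 10 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  Y <- X %*% t(R) * 1.05 + matrix(c(20, -10), 50, 2, byrow = TRUE)
  r <- register_affine(X, Y)
  expect_lt(symmetric_distance_D(X, r$points), 0.5)
  expect_true(r$converged)
  # 10% spurious points
  Yo <- rbind(Y, matrix(runif(10, 0, 500), 5, 2))
  ro <- register_affine(X, Yo)
  expect_lt(set_distance_d(X, ro$points), 2)
  # tiny sets pass through untouched
  rs <- register_affine(X[1:2, ], Y[1:2, ])
  expect_true(rs$skipped)
  expect_equal(rs$points, Y[1:2, ])
})

test_that("registration does not worsen the set distance under affine motion", {
  set.seed(43)
  for (rep in 1:5) {
    X <- matrix(runif(80, 0, 400), 40, 2)
    th <- runif(1, -0.2, 0.2)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    Y <- X %*% t(R) * runif(1, 0.95, 1.05) +
      matrix(runif(2, -15, 15), 40, 2, byrow = TRUE)
    before <- symmetric_distance_D(X, Y)
    after <- symmetric_distance_D(X, register_affine(X, Y)$points)
    expect_lte(after, before + 1e-6)
  }
})

test_that("set distances follow the median-of-nearest definition", {
  A <- rbind(c(0, 0), c(50, 0), c(0, 50))
  expect_equal(set_distance_d(A, A), 0)
  expect_equal(symmetric_distance_D(A, A), 0)
  # pure translation of well-separated points
  B <- sweep(A, 2, c(-3, -4))
  expect_equal(set_distance_d(A, B), 5)
  # asymmetry and even-count median
  A1 <- rbind(c(0, 0)); B1 <- rbind(c(0, 0), c(100, 0))
  expect_equal(set_distance_d(A1, B1), 0)
  expect_equal(set_distance_d(B1, A1), 50)
  expect_equal(symmetric_distance_D(A1, B1), 25)
  expect_identical(set_distance_d(A1, matrix(numeric(), 0, 2)), Inf)
  set.seed(44)
  for (rep in 1:20) {
    P <- matrix(runif(20, 0, 100), 10, 2)
    Q <- matrix(runif(16, 0, 100), 8, 2)
    expect_equal(symmetric_distance_D(P, Q), symmetric_distance_D(Q, P))
  }
})

test_that("distance matrix is zero for identical frames and blocky across a break", {
  f <- data.frame(x_e = runif(10, 0, 200), y_e = runif(10, 0, 200))
  static <- replicate(4, f, simplify = FALSE)
  M <- build_distance_matrix(static)
  expect_true(all(M$m < 1e-6))
  expect_equal(diag(M$m), rep(0, 4))

  cfg <- sim_config(n_berries = 30, n_frames = 10, jitter_sd_px = 0.5,
                    jitter_sd_deg = 0.2, jitter_sd_scale = 0,
                    events = list(list(frame = 6, shuffle = TRUE)), seed = 9)
  det <- sim_detections(simulate_bunch(cfg))
  M <- build_distance_matrix(det)$m
  within1 <- M[1:5, 1:5][upper.tri(diag(5))]
  within2 <- M[6:10, 6:10][upper.tri(diag(5))]
  across <- M[1:5, 6:10]
  expect_lt(max(within1, within2), 8)
  expect_gt(min(across), max(within1, within2))
})

test_that("rigid rotation events are absorbed by affine registration", {
  cfg <- sim_config(n_berries = 30, n_frames = 8, jitter_sd_px = 0,
                    jitter_sd_deg = 0, jitter_sd_scale = 0, amplitude = 0,
                    events = list(list(frame = 5, rotation = 45)), seed = 10)
  det <- sim_detections(simulate_bunch(cfg))
  M <- build_distance_matrix(det)$m
  expect_lt(max(M), 1) # near-zero everywhere after registration
  # without registration the rotation splits the series in two blocks
  M0 <- build_distance_matrix(det, use_registration = FALSE)$m
  expect_gt(min(M0[1:4, 5:8]), 8)
})

test_that("matching tree construction follows the layered rule", {
  t1 <- build_matching_tree(matrix(0, 1, 1))
  expect_equal(t1$root, 1)
  expect_equal(sum(is.na(t1$parent)), 1)

  # all pairwise distances below theta: root plus two depth-1 children
  M <- matrix(1, 3, 3); diag(M) <- 0
  tr <- build_matching_tree(M, theta = 8, sizes = c(3, 2, 1))
  expect_equal(tr$root, 1) # ties on placement, most points wins
  expect_equal(sort(tr$depth), c(0, 1, 1))
  expect_false(any(tr$long_edge))

  # all distances above theta: long-distance edges only
  M <- matrix(100, 3, 3); diag(M) <- 0
  tr <- build_matching_tree(M, theta = 8, sizes = c(1, 1, 1))
  expect_equal(sum(tr$long_edge), 2)
  expect_equal(tr$n_before_ld, 1)

  # spanning + depth consistency on random matrices
  set.seed(45)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    M <- matrix(runif(n * n, 0, 20), n, n); diag(M) <- 0
    tr <- build_matching_tree(M, theta = 8, sizes = rep(1, n))
    expect_equal(sort(tr$order), 1:n)
    for (i in setdiff(1:n, tr$root)) {
      expect_equal(tr$depth[i], tr$depth[tr$parent[i]] + 1)
    }
    expect_equal(tr$depth[tr$root], 0)
  }
})

test_that("root selection prefers the larger consistent block", {
  # frames 1..8 mutually close, 9..13 mutually close, far across
  n <- 13
  M <- matrix(50, n, n)
  M[1:8, 1:8] <- 2
  M[9:13, 9:13] <- 2
  diag(M) <- 0
  sizes <- rep(5, n)
  r <- select_root(M, sizes, theta = 8)
  expect_true(r %in% 1:8)
  # ties within the block broken by point count then index
  sizes[3] <- 9
  expect_equal(select_root(M, sizes, theta = 8), 3)
  expect_equal(select_root(matrix(0, 1, 1), 4, 8), 1)
})

test_that("label propagation keeps identities through gaps and is deterministic", {
  # static positions; berry 3 absent in frames 3-4, returns in 5
  base <- data.frame(x_e = c(0, 40, 80, 120), y_e = c(0, 0, 0, 0))
  series <- list(base, base, base[-3, ], base[-3, ], base)
  tr <- track_series(series, config = run_config())
  lab <- tr$labels
  expect_equal(lab[[1]], lab[[2]])
  expect_equal(lab[[5]], lab[[1]])
  # the absent berry's label is simply missing in frames 3-4
  expect_setequal(lab[[3]], lab[[1]][-3])
  tr2 <- track_series(series, config = run_config())
  expect_identical(tr$table, tr2$table)
})

test_that("simulated occlusion gap interrupts and then recovers a label", {
  cfg <- sim_config(n_berries = 25, n_frames = 12, jitter_sd_px = 1,
                    jitter_sd_deg = 0.3, jitter_sd_scale = 0, seed = 12)
  sim <- simulate_bunch(cfg)
  det <- sim_detections(sim)
  # force one berry out for frames 5..8 (full occlusion stand-in)
  gone <- det[[1]]$berry_id[1]
  for (f in 5:8) det[[f]] <- det[[f]][det[[f]]$berry_id != gone, , drop = FALSE]
  tr <- track_series(det)
  truth <- unlist(lapply(det, function(f) f$berry_id))
  sc <- tracking_score(tr$table, truth)
  expect_gte(sc[["T_p"]], 99)
  # find the label attached to the removed berry outside the gap
  tab <- tr$table
  tab$truth <- truth
  lab_gone <- unique(tab$label[tab$truth == gone & tab$label != -1])
  expect_equal(length(lab_gone), 1)
  frames_with <- sort(unique(tab$frame[tab$label == lab_gone]))
  expect_false(any(5:8 %in% frames_with))
  expect_true(all(c(1:4, 9:12) %in% frames_with))
})
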