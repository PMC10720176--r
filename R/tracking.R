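#' Time-lapse berry tracking
#'
#' Tracking assigns a persistent label to each berry across the image
#' series. Three cooperating pieces: (i) a greedy one-to-one matching of
#' ellipse centre points between two time steps, closest pairs first, pairs
#' farther than `delta` px discarded; (ii) an affine coherent point drift
#' (CPD) registration that absorbs global bunch/camera motion before
#' matching; (iii) a matching tree over time steps, built from a pairwise
#' set-distance matrix, that propagates labels from the most mutually
#' consistent frames outward instead of chronologically.
#'
#' A series is a list of per-frame data frames, each with (at least)
#' columns `x_e, y_e`; rows are the frame's berry observations.
#'
#' @name tracking
NULL

frame_points <- function(frame) {
  cbind(frame$x_e, frame$y_e)
}

#' Greedy one-to-one matching of two point sets
#'
#' Pairs are admitted in increasing Euclidean distance; every point is used
#' at most once and pairs with distance above `delta` are discarded. Ties
#' in distance are broken by lowest a-index, then lowest b-index.
#'
#' @param a,b two-column point matrices.
#' @param delta maximum matching distance (px).
#' @return two-column integer matrix of (a-index, b-index) pairs.
#' @export
greedy_match <- function(a, b, delta = 16) {
  a <- rbind(a[, 1:2, drop = FALSE]); b <- rbind(b[, 1:2, drop = FALSE])
  na <- nrow(a); nb <- nrow(b)
  empty <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("a", "b")))
  if (na == 0 || nb == 0) return(empty)
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  cand <- which(d <= delta, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  ord <- order(d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  out <- matrix(integer(), ncol = 2)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    out <- rbind(out, c(i, j))
  }
  colnames(out) <- c("a", "b")
  out
}

#' Affine coherent point drift registration
#'
#' EM point-set registration under an affine transform (Myronenko & Song's
#' CPD with an affine motion model and uniform outlier component). Returns
#' the moving set mapped onto the reference set.
#'
#' @param x_ref reference point matrix (n x 2).
#' @param y_mov moving point matrix (m x 2).
#' @param w outlier weight in `[0, 1)`.
#' @param tol relative change of the objective at which to stop.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE`.
#' @return list with `points` (registered `y_mov`), `B` (2 x 2 matrix),
#'   `t` (length-2 translation), `sigma2`, `iter`, `converged`, and
#'   `skipped = TRUE` when either set has fewer than 3 points (points are
#'   then returned unchanged).
#' @export
register_affine <- function(x_ref, y_mov, w = 0.1, tol = 1e-6,
                            max_iter = 200) {
  X <- rbind(x_ref[, 1:2, drop = FALSE]); Y <- rbind(y_mov[, 1:2, drop = FALSE])
  n <- nrow(X); m <- nrow(Y)
  if (n < 3 || m < 3) {
    return(list(points = Y, B = diag(2), t = c(0, 0), sigma2 = NA_real_,
                iter = 0L, converged = TRUE, skipped = TRUE))
  }
  D <- 2
  # normalise to zero mean / unit scale so the uniform outlier component is
  # commensurate with the Gaussian mixture; undone before returning
  mu_X0 <- colMeans(X); mu_Y0 <- colMeans(Y)
  sc_X <- sqrt(mean(rowSums(sweep(X, 2, mu_X0)^2)))
  sc_Y <- sqrt(mean(rowSums(sweep(Y, 2, mu_Y0)^2)))
  if (sc_X < .Machine$double.eps || sc_Y < .Machine$double.eps) {
    return(list(points = Y, B = diag(2), t = c(0, 0), sigma2 = NA_real_,
                iter = 0L, converged = TRUE, skipped = TRUE))
  }
  X <- sweep(X, 2, mu_X0) / sc_X
  Y <- sweep(Y, 2, mu_Y0) / sc_Y
  B <- diag(D); tvec <- c(0, 0)
  TY <- Y
  sigma2 <- sum(outer(X[, 1], Y[, 1], "-")^2 +
                outer(X[, 2], Y[, 2], "-")^2) / (D * n * m)
  L_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E-step: responsibilities of moving points for reference points
    d2 <- outer(TY[, 1], X[, 1], "-")^2 + outer(TY[, 2], X[, 2], "-")^2 # m x n
    num <- exp(-d2 / (2 * sigma2))
    cst <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * m / n
    den <- colSums(num) + cst
    L <- -sum(log(den)) + D * n * log(sigma2) / 2
    P <- sweep(num, 2, den, "/")
    Np <- sum(P)
    if (Np < .Machine$double.eps) break
    P1 <- rowSums(P)   # length m
    Pt1 <- colSums(P)  # length n
    mu_x <- colSums(Pt1 * X) / Np
    mu_y <- colSums(P1 * Y) / Np
    Xh <- sweep(X, 2, mu_x)
    Yh <- sweep(Y, 2, mu_y)
    A1 <- t(Xh) %*% t(P) %*% Yh
    A2 <- t(Yh) %*% (P1 * Yh)
    if (rcond(A2) < 1e-12) break
    B <- A1 %*% solve(A2)
    tvec <- mu_x - as.vector(B %*% mu_y)
    TY <- Y %*% t(B) + matrix(tvec, m, D, byrow = TRUE)
    sigma2_new <- (sum(Pt1 * rowSums(Xh^2)) - sum(diag(A1 %*% t(B)))) / (Np * D)
    sigma2 <- max(sigma2_new, 1e-10)
    if (is.finite(L_old) && abs(L_old - L) < tol * abs(L)) {
      converged <- TRUE
      break
    }
    L_old <- L
  }
  if (!converged && iter >= max_iter) {
    warning("CPD registration hit the iteration cap; returning best iterate")
  }
  # denormalise: map original-coordinate Y through the recovered transform
  B_full <- (sc_X / sc_Y) * B
  t_full <- mu_X0 + sc_X * tvec - as.vector(B_full %*% mu_Y0)
  TY_full <- sweep(TY * sc_X, 2, mu_X0, "+")
  list(points = TY_full, B = B_full, t = t_full, sigma2 = sigma2 * sc_X^2,
       iter = iter, converged = converged, skipped = FALSE)
}

#' Directed set distance (median of nearest-neighbour distances)
#'
#' `d(S_a, S_b)` = median over the points of `S_a` of the Euclidean
#' distance to their nearest neighbour in `S_b`. With an even count the
#' median is the mean of the two middle values.
#'
#' @param a,b two-column point matrices, both non-empty.
#' @return distance in px; `Inf` when either set is empty (undefined).
#' @export
set_distance_d <- function(a, b) {
  a <- rbind(a[, 1:2, drop = FALSE]); b <- rbind(b[, 1:2, drop = FALSE])
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  stats::median(sqrt(apply(d2, 1, min)))
}

#' Symmetric set distance
#'
#' Average of the two directed distances `d(a, b)` and `d(b, a)`.
#'
#' @inheritParams set_distance_d
#' @return distance in px.
#' @export
symmetric_distance_D <- function(a, b) {
  (set_distance_d(a, b) + set_distance_d(b, a)) / 2
}

#' Pairwise registered distance matrix of a series
#'
#' For every ordered frame pair `(i, j)`, registers `S_j` onto `S_i`
#' (skipped, with a flag, for frames with fewer than 3 points) and stores
#' the symmetric set distance of the registered pair.
#'
#' @param series list of per-frame data frames (or point matrices).
#' @param use_registration disable to measure raw (unregistered) distances.
#' @param config a [run_config()] (CPD settings).
#' @return list `m` (N x N matrix, zero diagonal) and `registered`
#'   (logical N x N, FALSE where registration was skipped).
#' @export
build_distance_matrix <- function(series, use_registration = TRUE,
                                  config = run_config()) {
  pts <- lapply(series, function(f) if (is.matrix(f)) f else frame_points(f))
  N <- length(pts)
  stopifnot(N >= 2)
  m <- matrix(0, N, N)
  reg <- matrix(TRUE, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      sj <- pts[[j]]
      if (use_registration) {
        r <- suppressWarnings(register_affine(pts[[i]], sj, w = config$cpd_w,
                                              tol = config$cpd_tol,
                                              max_iter = config$cpd_max_iter))
        sj <- r$points
        reg[i, j] <- !isTRUE(r$skipped)
      } else {
        reg[i, j] <- FALSE
      }
      m[i, j] <- symmetric_distance_D(pts[[i]], sj)
    }
  }
  list(m = m, registered = reg)
}

# Build a matching tree for a fixed root. Layered construction: at layer k,
# unplaced frames attach (closest first) to any placed frame of depth < k
# while min(M[i,j], M[j,i]) < theta; when no candidate qualifies, the
# single globally closest (unplaced, placed) pair is attached as a
# long-distance edge, opening the next layer.
build_tree_for_root <- function(M, root, theta = 8) {
  N <- nrow(M)
  Mmin <- pmin(M, t(M))
  parent <- rep(NA_integer_, N)
  depth <- rep(NA_integer_, N)
  long_edge <- rep(FALSE, N) # flag on the child of a long-distance edge
  placed <- logical(N)
  placed[root] <- TRUE
  depth[root] <- 0L
  order_placed <- root
  n_before_ld <- NA_integer_
  k <- 1L
  while (!all(placed)) {
    repeat {
      un <- which(!placed)
      el <- which(placed & depth < k)
      if (length(un) == 0 || length(el) == 0) break
      sub <- Mmin[un, el, drop = FALSE]
      bi <- arrayInd(which.min(sub), dim(sub))
      dmin <- sub[bi]
      if (!(dmin < theta)) break
      child <- un[bi[1]]; par <- el[bi[2]]
      parent[child] <- par
      depth[child] <- depth[par] + 1L
      placed[child] <- TRUE
      order_placed <- c(order_placed, child)
    }
    if (all(placed)) break
    un <- which(!placed); pl <- which(placed)
    sub <- Mmin[un, pl, drop = FALSE]
    bi <- arrayInd(which.min(sub), dim(sub))
    child <- un[bi[1]]; par <- pl[bi[2]]
    if (is.na(n_before_ld)) n_before_ld <- sum(placed)
    parent[child] <- par
    depth[child] <- depth[par] + 1L
    long_edge[child] <- TRUE
    placed[child] <- TRUE
    order_placed <- c(order_placed, child)
    k <- k + 1L
  }
  if (is.na(n_before_ld)) n_before_ld <- N
  list(root = root, parent = parent, depth = depth, long_edge = long_edge,
       order = order_placed, n_before_ld = n_before_ld, theta = theta)
}

#' Select the tree root
#'
#' Every frame is tried as root; the winner places the most nodes in the
#' tree before the first long-distance edge, ties broken by the largest
#' point count of the root frame, remaining ties by the smallest frame
#' index.
#'
#' @param M N x N distance matrix.
#' @param sizes integer vector of points per frame.
#' @param theta tree threshold (px).
#' @return the root frame index.
#' @export
select_root <- function(M, sizes, theta = 8) {
  N <- nrow(M)
  if (N == 1) return(1L)
  score <- vapply(seq_len(N), function(r)
    build_tree_for_root(M, r, theta)$n_before_ld, integer(1))
  best <- which(score == max(score))
  best[order(-sizes[best], best)][1]
}

#' Build the matching tree of a series
#'
#' @param M N x N distance matrix (list from [build_distance_matrix()] or a
#'   plain matrix).
#' @param theta distance threshold (px) controlling tree width vs depth.
#' @param sizes points per frame (for root selection); defaults to zeros.
#' @param root optional fixed root; selected exhaustively when `NULL`.
#' @return list with `root`, `parent`, `depth`, `long_edge`, `order`,
#'   `n_before_ld`, `theta`.
#' @export
build_matching_tree <- function(M, theta = 8, sizes = NULL, root = NULL) {
  if (is.list(M) && !is.matrix(M)) M <- M$m
  N <- nrow(M)
  if (is.null(sizes)) sizes <- rep(0L, N)
  if (is.null(root)) root <- select_root(M, sizes, theta)
  build_tree_for_root(M, root, theta)
}

#' Propagate labels along the matching tree
#'
#' Labels are initialised one per observation of the root frame (integer
#' ids in reading order) and propagated edge by edge in the order frames
#' were attached to the tree: the child frame is registered onto its
#' parent, centre points are greedily matched, and a child observation
#' inherits the label of the parent observation it matches (when that
#' parent observation is labelled). Unmatched observations stay unlabelled.
#'
#' @param series list of per-frame data frames with `x_e, y_e`.
#' @param tree a [build_matching_tree()] result.
#' @param use_registration register child onto parent before matching.
#' @param config a [run_config()] (`delta`, CPD settings).
#' @return list `labels`: per-frame integer vectors (`NA` = unlabelled);
#'   `n_labels`: number of labels initialised at the root.
#' @export
propagate_labels <- function(series, tree, use_registration = TRUE,
                             config = run_config()) {
  pts <- lapply(series, function(f) if (is.matrix(f)) f else frame_points(f))
  N <- length(pts)
  labels <- lapply(pts, function(p) rep(NA_integer_, nrow(p)))
  labels[[tree$root]] <- seq_len(nrow(pts[[tree$root]]))
  for (child in tree$order[-1]) {
    par <- tree$parent[child]
    cp <- pts[[child]]
    if (use_registration) {
      cp <- suppressWarnings(register_affine(pts[[par]], cp,
                                             w = config$cpd_w,
                                             tol = config$cpd_tol,
                                             max_iter = config$cpd_max_iter))$points
    }
    pairs <- greedy_match(pts[[par]], cp, delta = config$delta)
    for (k in seq_len(nrow(pairs))) {
      lab <- labels[[par]][pairs[k, 1]]
      if (!is.na(lab)) labels[[child]][pairs[k, 2]] <- lab
    }
  }
  list(labels = labels, n_labels = length(labels[[tree$root]]))
}

#' Track a berry series end to end
#'
#' Combines the distance matrix, matching tree and label propagation.
#' `use_tree = FALSE` falls back to chronological frame-to-frame
#' propagation from the first frame (the baseline ordering);
#' `use_registration = FALSE` matches raw coordinates. The four
#' combinations reproduce the baseline / +registration / +tree /
#' +both method variants.
#'
#' @param series list of per-frame data frames with `x_e, y_e` columns.
#' @param use_registration,use_tree stage switches.
#' @param config a [run_config()].
#' @return list with `labels` (per-frame integer vectors, `NA` unlabelled),
#'   `tree` (`NULL` for the chronological baseline), `distance_matrix`
#'   (`NULL` likewise) and `table` (long data frame `frame, obs, label`
#'   with `label = -1` for unlabelled observations).
#' @export
track_series <- function(series, use_registration = TRUE, use_tree = TRUE,
                         config = run_config()) {
  N <- length(series)
  stopifnot(N >= 2)
  dm <- NULL
  if (use_tree) {
    dm <- build_distance_matrix(series, use_registration = use_registration,
                                config = config)
    sizes <- vapply(series, nrow, integer(1))
    tree <- build_matching_tree(dm, theta = config$theta, sizes = sizes)
  } else {
    # chronological chain rooted at the first frame
    tree <- list(root = 1L, parent = c(NA_integer_, seq_len(N - 1)),
                 depth = 0:(N - 1), long_edge = rep(FALSE, N),
                 order = seq_len(N), n_before_ld = N, theta = config$theta)
  }
  prop <- propagate_labels(series, tree, use_registration = use_registration,
                           config = config)
  tab <- do.call(rbind, lapply(seq_len(N), function(t) {
    n <- nrow(series[[t]])
    if (n == 0) return(NULL)
    data.frame(frame = t, obs = seq_len(n),
               label = ifelse(is.na(prop$labels[[t]]), -1L, prop$labels[[t]]))
  }))
  list(labels = prop$labels, tree = if (use_tree) tree else NULL,
       distance_matrix = dm, table = tab)
}
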