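#' Accuracy metrics for detection, segmentation and tracking
#'
#' @name evaluation
NULL

#' Match predicted against ground-truth ellipses
#'
#' One-to-one greedy matching by descending IoU; pairs with IoU strictly
#' above `iou_min` are true positives, unmatched predictions false
#' positives, unmatched truths false negatives. Ties are broken by
#' prediction order.
#'
#' @param pred,truth data frames of ellipses (`x_e, y_e, w_e, h_e, a_e`).
#' @param iou_min IoU threshold (exclusive).
#' @return list `TP`, `FP`, `FN`, and `pairs` (matrix of matched
#'   pred/truth row indices).
#' @export
match_instances <- function(pred, truth, iou_min = 0.5) {
  np <- if (is.null(pred)) 0L else nrow(pred)
  nt <- if (is.null(truth)) 0L else nrow(truth)
  if (np == 0 || nt == 0) {
    return(list(TP = 0L, FP = np, FN = nt,
                pairs = matrix(integer(), ncol = 2,
                               dimnames = list(NULL, c("pred", "truth")))))
  }
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) {
    ei <- pred[i, c("x_e", "y_e", "w_e", "h_e", "a_e")]
    for (j in seq_len(nt)) {
      iou[i, j] <- ellipse_iou(ei, truth[j, c("x_e", "y_e", "w_e", "h_e", "a_e")])
    }
  }
  cand <- which(iou > iou_min, arr.ind = TRUE)
  pairs <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("pred", "truth")))
  if (nrow(cand)) {
    ord <- order(-iou[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    up <- logical(np); ut <- logical(nt)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (up[i] || ut[j]) next
      up[i] <- TRUE; ut[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  tp <- nrow(pairs)
  list(TP = tp, FP = np - tp, FN = nt - tp, pairs = pairs)
}

#' Precision, recall and F1-score from confusion counts
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`, all as percentages.
#'
#' @param counts list with `TP`, `FP`, `FN`.
#' @return named numeric vector `precision, recall, f1` (percent); `NA`
#'   (with a warning) where a denominator is zero.
#' @export
prf <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (tp + fp == 0 || tp + fn == 0) {
    warning("undefined precision/recall: zero denominator")
    return(c(precision = NA_real_, recall = NA_real_, f1 = NA_real_))
  }
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = 100 * p, recall = 100 * r, f1 = 100 * f1)
}

#' Agreement metrics for paired area measurements
#'
#' @param pred,truth paired numeric vectors (predicted and ground-truth
#'   areas); pairs with zero truth are skipped with a warning.
#' @return named vector `bias, rmse, mape, r2` (`mape` in percent).
#' @export
area_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  ok <- truth != 0
  if (any(!ok)) warning(sum(!ok), " pair(s) with zero truth area skipped")
  pred <- pred[ok]; truth <- truth[ok]
  stopifnot(length(pred) >= 2)
  err <- pred - truth
  c(bias = mean(err),
    rmse = sqrt(mean(err^2)),
    mape = 100 * mean(abs(err) / truth),
    r2 = 1 - sum(err^2) / sum((truth - mean(truth))^2))
}

#' Tracking coverage and precision against ground-truth identities
#'
#' Coverage `T_c` is the percentage of observations that received a track
#' label; precision `T_p` the percentage of labels all of whose
#' observations designate the same true berry.
#'
#' @param track_table long data frame `frame, obs, label` (`label = -1` or
#'   `NA` for unlabelled) as produced by [track_series()].
#' @param truth_ids vector of true berry ids aligned with the rows of
#'   `track_table`.
#' @return named vector `T_c, T_p` (percent; `T_p` is `NA` with no labels).
#' @export
tracking_score <- function(track_table, truth_ids) {
  stopifnot(nrow(track_table) == length(truth_ids))
  lab <- track_table$label
  lab[is.na(lab)] <- -1L
  tc <- 100 * mean(lab != -1L)
  labs <- unique(lab[lab != -1L])
  if (length(labs) == 0) return(c(T_c = tc, T_p = NA_real_))
  pure <- vapply(labs, function(l)
    length(unique(truth_ids[lab == l])) == 1L, logical(1))
  c(T_c = tc, T_p = 100 * mean(pure))
}
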