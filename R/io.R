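#' File formats
#'
#' All tabular interchange uses comma-separated UTF-8 CSV with a header
#' and "." decimal. Detections: one row per berry observation
#' (`frame, berry_id, x_e, y_e, w_e, h_e, a_e, score`, plus feature
#' columns when present). Tracks: the same with a `label` column
#' (`-1` = unlabelled) and `time_days`. The matching tree and metrics are
#' JSON; the distance matrix a plain CSV of numbers.
#'
#' @name io-formats
NULL

#' Write / read a detections (ellipse) CSV
#'
#' @param detections data frame with at least
#'   `frame, x_e, y_e, w_e, h_e, a_e, score`.
#' @param path CSV file.
#' @export
write_detections <- function(detections, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @return `read_detections`: the detections data frame.
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "x_e", "y_e", "w_e", "h_e", "a_e")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("detections CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  d
}

#' Split a detections table into a per-frame series
#'
#' @param detections detections data frame with a `frame` column.
#' @return list of per-frame data frames ordered by frame index; frames
#'   with no detections are empty data frames.
#' @export
detections_to_series <- function(detections) {
  frames <- sort(unique(detections$frame))
  lapply(frames, function(f) detections[detections$frame == f, , drop = FALSE])
}

#' Write a matching tree as JSON
#'
#' @param tree a [build_matching_tree()] result.
#' @param path JSON file.
#' @export
write_tree <- function(tree, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(root = tree$root,
         parent = as.list(stats::setNames(tree$parent,
                                          seq_along(tree$parent))),
         depth = tree$depth,
         long_distance = which(tree$long_edge),
         order = tree$order,
         theta = tree$theta),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Write / read a distance matrix CSV
#'
#' @param m numeric matrix (or [build_distance_matrix()] result).
#' @param path CSV file.
#' @export
write_distance_matrix <- function(m, path) {
  if (is.list(m) && !is.matrix(m)) m <- m$m
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Write a metrics report as JSON
#'
#' @param metrics named list (e.g. `detection`, `segmentation`,
#'   `tracking` blocks).
#' @param path JSON file.
#' @export
write_metrics <- function(metrics, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
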