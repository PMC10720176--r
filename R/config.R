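#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Defaults are the
#' operating values of the published pipeline this package implements:
#' 416 px detector tiles placed at most 270 px apart, box NMS at IoU 0.70,
#' detection confidence threshold 0.89, vignette margin z = 0.75 with
#' 128 px vignettes, hue centring reference h_50 = 100 deg, edge-margin
#' rule dp = max(3, w_e/4) px, volume calibration 3.94e-6 mL/px^3,
#' matching radius delta = 16 px, tree threshold theta = 8 px, 8-day
#' smoothing window, 90% coverage filter, 10% MAPE exclusion and
#' 0.15/0.85 scaled-volume crossing levels.
#'
#' @param ... overrides for any of the defaults (partial matching not
#'   performed; unknown names are an error).
#' @return a named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    tile_size = 416,
    tile_spacing = 270,
    nms_iou = 0.70,
    conf_threshold = 0.89,
    vignette_z = 0.75,
    vignette_size = 128,
    h_50 = 100,
    dp_min = 3,
    dp_frac = 4, # dp = max(dp_min, w_e / dp_frac)
    ml_per_px3 = 3.94e-6,
    delta = 16,
    theta = 8,
    cpd_w = 0.1,
    cpd_tol = 1e-6,
    cpd_max_iter = 200,
    smooth_window_days = 8,
    baseline_days = 8,
    min_coverage = 0.90,
    mape_drop = 0.10,
    level_low = 0.15,
    level_high = 0.85,
    seed = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Write a run manifest
#'
#' Records the resolved configuration, the seed and the package version so
#' that a run is fully reproducible from its manifest.
#'
#' @param config a [run_config()].
#' @param path output JSON file.
#' @param extra named list of additional fields (input paths, scenario...).
#' @export
write_manifest <- function(config, path, extra = list()) {
  m <- c(list(tool = "berrytrack",
              version = as.character(utils::packageVersion("berrytrack")),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         list(config = unclass(config)), extra)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
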