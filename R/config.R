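#' Read a pipeline configuration file
#'
#' The pipeline is configured by a single JSON file with optional sections
#' \code{backbone}, \code{temporal}, \code{head}, \code{refinement},
#' \code{eval}, \code{train}, \code{augment} and \code{scene}; omitted
#' sections (or fields) take the package defaults. Used by the command-line
#' driver; programmatic callers can build the config objects directly.
#'
#' @param path JSON config file, or NULL for all defaults.
#' @return a list of config objects: \code{detector}, \code{refinement},
#'   \code{train}, \code{augment}, \code{scene}, \code{eval} (a plain list
#'   with \code{iou_min_2d}, \code{iou_min_4d}, \code{run_length}).
#' @export
read_pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else jsonlite::fromJSON(path)
  take <- function(section, fn) {
    args <- raw[[section]] %||% list()
    do.call(fn, args)
  }
  detector <- detector_config(backbone = take("backbone", backbone_config),
                              temporal = take("temporal", temporal_config),
                              head = take("head", head_config))
  ev <- raw$eval %||% list()
  list(detector = detector,
       refinement = take("refinement", refinement_config),
       train = take("train", train_config),
       augment = take("augment", augment_spec),
       scene = take("scene", scene_spec),
       eval = list(iou_min_2d = ev$iou_min_2d %||% 0.6,
                   iou_min_4d = ev$iou_min_4d %||% 0.5,
                   run_length = ev$run_length %||% 5L))
}

#' Serialize an evaluation report pair as JSON
#'
#' @param reports named list of \code{eval_report_2d} / \code{eval_report_4d}
#'   objects (or plain lists).
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_report <- function(reports, path) {
  strip <- function(x) {
    if (inherits(x, "eval_report_2d") || inherits(x, "eval_report_4d"))
      x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  jsonlite::write_json(strip(reports), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
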