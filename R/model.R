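#' Full detector configuration
#'
#' Bundles the backbone, temporal-aggregation and head configurations into
#' one detector. The backbone must expose all three output scales {4, 8, 16}
#' (i.e. at least three levels); a two-level backbone builds as a graph but
#' cannot drive the detector.
#'
#' @param backbone a \code{\link{backbone_config}}.
#' @param temporal a \code{\link{temporal_config}}.
#' @param head a \code{\link{head_config}}.
#' @return a \code{detector_config} list.
#' @export
detector_config <- function(backbone = backbone_config(),
                            temporal = temporal_config(),
                            head = head_config()) {
  graph <- build_graph(backbone)
  if (!all(c(4, 8, 16) %in% graph$output_scales))
    stop("config error: detection needs backbone output scales {4, 8, 16}; ",
         "this backbone only provides {",
         paste(graph$output_scales, collapse = ", "), "}")
  if (backbone$in_channels != temporal$slice_span)
    stop("backbone in_channels (", backbone$in_channels,
         ") must equal the 2.5D slice span (", temporal$slice_span, ")")
  structure(list(backbone = backbone, temporal = temporal, head = head),
            class = "detector_config")
}

#' Initialise a detector with random weights
#'
#' All weights are drawn from a single seeded RNG stream, so the same seed
#' always yields the same network.
#'
#' @param config a \code{\link{detector_config}}.
#' @param seed integer seed for weight initialisation.
#' @return a \code{mito_detector} list with \code{config}, \code{graph},
#'   \code{params} and \code{seed}.
#' @export
detector_init <- function(config, seed = 1L) {
  graph <- build_graph(config$backbone)
  store <- nn_params()
  with_seed(seed, {
    backbone_init(store, config$backbone)
    temporal_init(store, config$backbone, config$temporal)
    head_init(store, 3L * config$temporal$proj_channels, config$head)
  })
  structure(list(config = config, graph = graph, params = store,
                 seed = as.integer(seed)),
            class = "mito_detector")
}

#' @export
print.mito_detector <- function(x, ...) {
  npar <- sum(vapply(x$params$val, length, numeric(1)))
  cat(sprintf("<mito_detector> %d levels, %d parameters, seed %d\n",
              x$config$backbone$I, npar, x$seed))
  invisible(x)
}

# backbone feature maps of one 2.5D stack as plain arrays (inference path,
# cacheable across overlapping temporal windows)
detector_backbone_maps <- function(model, stack) {
  tp <- nn_tape(model$params, grad = FALSE)
  res <- backbone_forward(tp, op_input(tp, stack), model$graph)
  lapply(res$outputs, function(n) n$v)
}

# temporal aggregation + head on per-frame plain-array feature maps
detector_head_from_maps <- function(model, maps, center) {
  tp <- nn_tape(model$params, grad = FALSE)
  per_frame <- lapply(maps, function(m) lapply(m, function(v) op_input(tp, v)))
  temporal <- clstm_aggregate(tp, per_frame, center, model$config$temporal)
  fused <- fuse_scales(tp, temporal, model$config$temporal)
  pred <- head_forward(tp, fused, model$config$head)
  list(heatmap = pred$heatmap$v, size = pred$size$v, offset = pred$offset$v)
}

#' Run the detector over one temporal window
#'
#' Applies the shared-weight backbone to each of the window's 2.5D stacks,
#' aggregates the three scales with the bidirectional CLSTMs, fuses them to
#' one scale-4 map and evaluates the center-point head.
#'
#' @param model a \code{mito_detector}.
#' @param window a window from \code{\link{extract_window}} (or a list with
#'   \code{frames} and \code{center}).
#' @param grad record a tape for training (internal use).
#' @return with \code{grad = FALSE}: a list of plain arrays heatmap / size /
#'   offset; with \code{grad = TRUE}: a list with the tape and node handles.
#' @export
detector_forward <- function(model, window, grad = FALSE) {
  tp <- nn_tape(model$params, grad = grad)
  per_frame <- lapply(window$frames, function(f) {
    backbone_forward(tp, op_input(tp, f), model$graph)$outputs
  })
  temporal <- clstm_aggregate(tp, per_frame, window$center,
                              model$config$temporal)
  fused <- fuse_scales(tp, temporal, model$config$temporal)
  pred <- head_forward(tp, fused, model$config$head)
  if (!grad)
    return(list(heatmap = pred$heatmap$v, size = pred$size$v,
                offset = pred$offset$v))
  list(tape = tp, pred = pred, fused = fused)
}

#' Save / load a detector checkpoint
#'
#' Checkpoints are plain-text JSON carrying the configuration, the seed and
#' every parameter tensor, so they survive text-only transport and reload
#' bit-exactly (doubles are serialized at full precision).
#'
#' @param model a \code{mito_detector}.
#' @param path checkpoint file path (.json).
#' @return \code{load_checkpoint}: a \code{mito_detector}.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    config = list(backbone = unclass(model$config$backbone),
                  temporal = unclass(model$config$temporal),
                  head = unclass(model$config$head)),
    seed = model$seed,
    params = params_to_list(model$params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  bb <- x$config$backbone
  config <- detector_config(
    backbone = backbone_config(I = bb$I, J = bb$J,
                               channels_per_level = bb$channels_per_level,
                               in_channels = bb$in_channels,
                               use_deformable = isTRUE(bb$use_deformable)),
    temporal = do.call(temporal_config, x$config$temporal),
    head = do.call(head_config,
                   x$config$head[setdiff(names(x$config$head), "stride")]))
  model <- structure(list(config = config, graph = build_graph(config$backbone),
                          params = params_from_list(x$params),
                          seed = as.integer(x$seed)),
                     class = "mito_detector")
  model
}
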