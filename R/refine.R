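#' 4D refinement configuration
#'
#' After per-slice decoding, each box's confidence is re-scored from the
#' distance-weighted agreement of binarized detections in its spatio-temporal
#' neighbourhood: slices \code{s + j}, \code{|j| <= N}, and frames
#' \code{t + k}, \code{|k| <= T}. The defaults N = 4 and T = 6 are the
#' operating point the method was tuned to.
#'
#' @param N spatial neighbour radius in slices (>= 0).
#' @param T temporal neighbour radius in frames (>= 0); N and T must not
#'   both be 0.
#' @param binarize_threshold confidence binarization threshold (inclusive).
#' @param associate_iou minimum IoU to associate a neighbour box with the
#'   target box.
#' @param keep_threshold refined-score cutoff below which boxes are dropped.
#' @return a \code{refinement_config} list.
#' @export
refinement_config <- function(N = 4L, T = 6L, binarize_threshold = 0.5,
                              associate_iou = 0.3, keep_threshold = 0.5) {
  N <- as.integer(N); T <- as.integer(T)
  if (N < 0 || T < 0 || (N == 0 && T == 0))
    stop("refinement needs N >= 0, T >= 0 and not both 0")
  for (thr in c(binarize_threshold, associate_iou, keep_threshold))
    if (thr <= 0 || thr >= 1) stop("refinement thresholds must lie in (0, 1)")
  structure(list(N = N, T = T, binarize_threshold = binarize_threshold,
                 associate_iou = associate_iou,
                 keep_threshold = keep_threshold),
            class = "refinement_config")
}

#' Binarize a confidence score
#'
#' @param p confidence(s) in [0, 1].
#' @param threshold inclusive cutoff: 1 when \code{p >= threshold}, else 0.
#' @return 0/1 numeric vector.
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(all(p >= 0 & p <= 1))
  as.numeric(p >= threshold)
}

#' Distance weight of a spatio-temporal neighbour
#'
#' \code{W = 1 - sqrt(j^2 + k^2) / sqrt(N^2 + T^2)}: 1 at the target cell,
#' falling to 0 at the (N, T) corner of the neighbourhood.
#'
#' @param j slice offset, \code{|j| <= N}.
#' @param k frame offset, \code{|k| <= T}.
#' @param N,T neighbourhood radii.
#' @return weight(s) in [0, 1].
#' @export
neighbour_weight <- function(j, k, N = 4, T = 6) {
  if (any(abs(j) > N) || any(abs(k) > T))
    stop("neighbour offsets must satisfy |j| <= N, |k| <= T")
  1 - sqrt(j^2 + k^2) / sqrt(N^2 + T^2)
}

#' Associate a target box with its spatio-temporal neighbours
#'
#' For every in-volume neighbourhood cell (j, k), the detection at slice
#' \code{s + j}, frame \code{t + k} with the highest IoU against the target's
#' planar extent (at least \code{associate_iou}) contributes its binarized
#' confidence; cells with no association contribute 0. Cells outside the
#' volume are excluded entirely (truncated window).
#'
#' @param target a single-row box table.
#' @param det_index detections split by (t, s) (internal index from
#'   \code{\link{refine}}), or a box table.
#' @param n_slices,n_frames volume extents bounding the window.
#' @param config a \code{\link{refinement_config}}.
#' @return a data frame with columns j, k, p_hat (one row per in-volume cell).
#' @export
associate_neighbours <- function(target, det_index, n_slices, n_frames,
                                 config = refinement_config()) {
  if (is.data.frame(det_index)) det_index <- split_by_frame_slice(det_index)
  cells <- expand.grid(j = -config$N:config$N, k = -config$T:config$T)
  s2 <- target$s + cells$j
  t2 <- target$t + cells$k
  keep <- s2 >= 0 & s2 < n_slices & t2 >= 0 & t2 < n_frames
  cells <- cells[keep, , drop = FALSE]
  s2 <- s2[keep]; t2 <- t2[keep]
  p_hat <- numeric(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    grp <- det_index[[paste(t2[r], s2[r], sep = ":")]]
    if (is.null(grp) || nrow(grp) == 0) next
    ious <- box_iou_matrix(grp, target)[, 1]
    best <- which.max(ious)
    if (ious[best] >= config$associate_iou)
      p_hat[r] <- binarize(grp$p[best], config$binarize_threshold)
  }
  data.frame(j = cells$j, k = cells$k, p_hat = p_hat)
}

#' Refined confidence from a neighbour contribution map
#'
#' The refined score is the distance-weighted mean of the binarized
#' neighbour confidences: \code{sum(W * p_hat) / sum(W)} over the map's
#' cells. If the map degenerates to the single zero-weight corner cell, the
#' target's own binarized confidence is returned.
#'
#' @param contributions data frame with columns j, k, p_hat (must contain
#'   the (0, 0) cell).
#' @param config a \code{\link{refinement_config}}.
#' @return refined confidence in [0, 1].
#' @export
refine_score <- function(contributions, config = refinement_config()) {
  stopifnot(nrow(contributions) > 0,
            any(contributions$j == 0 & contributions$k == 0))
  w <- neighbour_weight(contributions$j, contributions$k, config$N, config$T)
  if (sum(w) <= 0)
    return(contributions$p_hat[contributions$j == 0 & contributions$k == 0][1])
  sum(w * contributions$p_hat) / sum(w)
}

#' Refine a detection set over its 4D context
#'
#' Every box gains \code{p_hat} (its own binarized confidence) and
#' \code{p_refined} (the distance-weighted neighbourhood agreement); boxes
#' with \code{p_refined >= keep_threshold} are kept, geometry unchanged.
#' Isolated spurious detections — boxes with no agreeing neighbours across
#' slices or frames — end far below the cutoff and are removed, while boxes
#' belonging to a persistent mitotic event are retained.
#'
#' @param detections a box table covering a 4D extent.
#' @param n_slices,n_frames extents of the source volume (bound the
#'   neighbourhood window; out-of-volume cells drop from both sums).
#' @param config a \code{\link{refinement_config}}.
#' @param keep drop boxes below the cutoff (default TRUE); with FALSE the
#'   full re-scored table is returned.
#' @return a box table with extra columns p_hat and p_refined.
#' @export
refine <- function(detections, n_slices, n_frames,
                   config = refinement_config(), keep = TRUE) {
  if (nrow(detections) == 0) {
    out <- as.data.frame(detections)
    out$p_hat <- numeric(0)
    out$p_refined <- numeric(0)
    return(validate_boxes(out))
  }
  det_index <- split_by_frame_slice(detections)
  out <- as.data.frame(detections)
  out$p_hat <- binarize(out$p, config$binarize_threshold)
  out$p_refined <- vapply(seq_len(nrow(out)), function(r) {
    refine_score(associate_neighbours(out[r, ], det_index, n_slices,
                                      n_frames, config), config)
  }, numeric(1))
  if (keep) out <- out[out$p_refined >= config$keep_threshold, , drop = FALSE]
  rownames(out) <- NULL
  validate_boxes(out)
}
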