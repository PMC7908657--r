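#' Composite detection score
#'
#' Two conventions are provided. \code{"mean"} is the arithmetic mean
#' \code{(P + R) / 2} — the convention under which the published comparison
#' tables' composite column reproduces exactly from their printed precision
#' and recall. \code{"harmonic"} is the standard F1 score
#' \code{2 P R / (P + R)} (0 when both are 0). Reports carry both.
#'
#' @param precision,recall values in [0, 1].
#' @param convention "mean" or "harmonic".
#' @return the composite score.
#' @examples
#' composite_score(0.0411, 0.7221, "mean")   # 0.3816
#' composite_score(0.7883, 0.7751, "mean")   # 0.7817
#' @export
composite_score <- function(precision, recall,
                            convention = c("mean", "harmonic")) {
  convention <- match.arg(convention)
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  if (convention == "mean") (precision + recall) / 2
  else ifelse(precision + recall == 0, 0,
              2 * precision * recall / (precision + recall))
}

#' Slice-wise 2D detection evaluation
#'
#' Detections and annotations are matched per (t, s) context with
#' confidence-ordered greedy IoU matching; a detection is a true positive
#' when its IoU with an unclaimed ground-truth box strictly exceeds
#' \code{iou_min} (default 0.6). Unmatched detections are false positives
#' and unmatched annotations false negatives.
#'
#' @param detections,annotations box tables.
#' @param iou_min IoU threshold (strict inequality).
#' @return an \code{eval_report_2d} list: tp, fp, fn, precision, recall,
#'   score_mean ((P+R)/2) and score_harmonic (2PR/(P+R)); precision/recall
#'   are 0 when their denominator is 0.
#' @export
evaluate_2d <- function(detections, annotations, iou_min = 0.6) {
  det_groups <- split_by_frame_slice(detections)
  ann_groups <- split_by_frame_slice(annotations)
  tp <- 0L
  for (key in union(names(det_groups), names(ann_groups))) {
    d <- det_groups[[key]]; a <- ann_groups[[key]]
    if (is.null(d) || is.null(a)) next
    m <- greedy_match(d, a, iou_min, strict = TRUE)
    tp <- tp + sum(!is.na(m$match))
  }
  fp <- nrow(detections) - tp
  fn <- nrow(annotations) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 score_mean = composite_score(precision, recall, "mean"),
                 score_harmonic = composite_score(precision, recall, "harmonic"),
                 iou_min = iou_min),
            class = "eval_report_2d")
}

#' @export
print.eval_report_2d <- function(x, ...) {
  cat(sprintf("2D evaluation (IoU > %.2f)\n", x$iou_min))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f\n", x$precision, x$recall))
  cat(sprintf("  composite (mean) %.4f  F1 (harmonic) %.4f\n",
              round(x$score_mean, 4), round(x$score_harmonic, 4)))
  invisible(x)
}

# link one frame's detections into slice-contiguous regions by greedy IoU
# between consecutive slices; returns a list of box tables
link_regions_frame <- function(det_t, associate_iou) {
  slices <- sort(unique(det_t$s))
  regions <- list()
  open <- list()  # regions whose last box sits at the previous slice
  prev_s <- NULL
  for (s in slices) {
    cur <- det_t[det_t$s == s, , drop = FALSE]
    new_open <- list()
    if (!is.null(prev_s) && s == prev_s + 1 && length(open) > 0) {
      last_boxes <- do.call(rbind, lapply(open, function(r) r[nrow(r), ]))
      m <- greedy_match(cur, last_boxes, associate_iou)
      for (ci in seq_len(nrow(cur))) {
        if (!is.na(m$match[ci])) {
          ri <- m$match[ci]
          open[[ri]] <- rbind(open[[ri]], cur[ci, ])
          new_open[[length(new_open) + 1]] <- open[[ri]]
          open[ri] <- list(NULL)
        }
      }
      for (r in open) if (!is.null(r)) regions[[length(regions) + 1]] <- r
      unmatched <- which(is.na(m$match))
      for (ci in unmatched)
        new_open[[length(new_open) + 1]] <- cur[ci, , drop = FALSE]
    } else {
      for (r in open) regions[[length(regions) + 1]] <- r
      for (ci in seq_len(nrow(cur)))
        new_open[[length(new_open) + 1]] <- cur[ci, , drop = FALSE]
    }
    open <- new_open
    prev_s <- s
  }
  for (r in open) regions[[length(regions) + 1]] <- r
  regions
}

# best mean IoU over any run_length consecutive slices shared by a region
# and a reference box table; NA if no such run exists
best_run_mean_iou <- function(region, ref, run_length) {
  shared <- intersect(region$s, ref$s)
  if (length(shared) < run_length) return(NA_real_)
  shared <- sort(shared)
  ious <- vapply(shared, function(s) {
    box_iou(region[region$s == s, ][1, ], ref[ref$s == s, ][1, ])
  }, numeric(1))
  best <- NA_real_
  runs <- split(seq_along(shared), cumsum(c(1, diff(shared) != 1)))
  for (idx in runs) {
    if (length(idx) < run_length) next
    for (a in 1:(length(idx) - run_length + 1)) {
      m <- mean(ious[idx[a:(a + run_length - 1)]])
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}

# mean IoU between consecutive boxes of a region (self-consistency)
region_self_iou <- function(region) {
  if (nrow(region) < 2) return(0)
  mean(vapply(seq_len(nrow(region) - 1), function(i)
    box_iou(region[i, ], region[i + 1, ]), numeric(1)))
}

#' 4D event-level detection evaluation
#'
#' Detections within each frame are linked across adjacent slices into
#' regions (greedy IoU). A ground-truth mitotic event counts as a true
#' positive if, in at least one of its frames, a region overlaps it over
#' \code{run_length} (default 5) continuous slices with mean per-slice IoU
#' strictly above \code{iou_min} (default 0.5); otherwise it is a false
#' negative. Regions spanning \code{run_length} continuous slices whose
#' self-consistency IoU (mean IoU of consecutive slices) exceeds
#' \code{iou_min} but which credit no event are false positives; such
#' regions are linked across adjacent frames and each linked track counts
#' once.
#'
#' @param detections box table (typically refined).
#' @param annotations event-linked ground-truth box table (event_id set).
#' @param iou_min average-IoU threshold (strict).
#' @param run_length required number of continuous slices.
#' @param associate_iou IoU for slice-to-slice (and FP frame-to-frame)
#'   linking.
#' @return an \code{eval_report_4d} list: tp, fn, fp, per-event detection
#'   flags, and ids of events too short in z to ever satisfy the rule.
#' @export
evaluate_4d <- function(detections, annotations, iou_min = 0.5,
                        run_length = 5L, associate_iou = 0.3) {
  ev_ids <- sort(unique(annotations$event_id[!is.na(annotations$event_id)]))
  detected <- stats::setNames(rep(FALSE, length(ev_ids)), ev_ids)
  short_events <- integer(0)
  for (e in ev_ids) {
    spans <- tapply(annotations$s[annotations$event_id == e],
                    annotations$t[annotations$event_id == e],
                    function(s) length(unique(s)))
    if (max(spans) < run_length) short_events <- c(short_events, e)
  }
  fp_tracks <- list()  # each: list(t, box) of linked FP regions
  for (t in sort(unique(detections$t))) {
    det_t <- detections[detections$t == t, , drop = FALSE]
    ann_t <- annotations[annotations$t == t, , drop = FALSE]
    regions <- link_regions_frame(det_t, associate_iou)
    for (region in regions) {
      credited <- FALSE
      for (e in ev_ids) {
        ref <- ann_t[!is.na(ann_t$event_id) & ann_t$event_id == e, ,
                     drop = FALSE]
        if (nrow(ref) == 0) next
        m <- best_run_mean_iou(region, ref, run_length)
        if (!is.na(m) && m > iou_min) {
          detected[as.character(e)] <- TRUE
          credited <- TRUE
        }
      }
      if (!credited && nrow(region) >= run_length &&
          region_self_iou(region) > iou_min) {
        rep_box <- region[ceiling(nrow(region) / 2), , drop = FALSE]
        linked <- FALSE
        for (i in seq_along(fp_tracks)) {
          tr <- fp_tracks[[i]]
          if (t - tr$t <= 1 &&
              box_iou(rep_box, tr$box) >= associate_iou) {
            fp_tracks[[i]]$t <- t
            fp_tracks[[i]]$box <- rep_box
            linked <- TRUE
            break
          }
        }
        if (!linked)
          fp_tracks[[length(fp_tracks) + 1]] <- list(t = t, box = rep_box)
      }
    }
  }
  tp <- sum(detected)
  structure(list(tp = tp, fn = length(ev_ids) - tp, fp = length(fp_tracks),
                 n_events = length(ev_ids), detected = detected,
                 short_events = short_events,
                 iou_min = iou_min, run_length = as.integer(run_length)),
            class = "eval_report_4d")
}

#' @export
print.eval_report_4d <- function(x, ...) {
  cat(sprintf("4D evaluation (mean IoU > %.2f over %d continuous slices)\n",
              x$iou_min, x$run_length))
  cat(sprintf("  events %d  TP %d  FN %d  FP %d\n",
              x$n_events, x$tp, x$fn, x$fp))
  if (length(x$short_events) > 0)
    cat("  note: event(s)", paste(x$short_events, collapse = ", "),
        "span fewer slices than the run length and cannot be credited\n")
  invisible(x)
}
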