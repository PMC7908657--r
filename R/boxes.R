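#' Box tables
#'
#' Detections and ground-truth annotations are kept in plain data frames with
#' one row per bounding box and columns
#' \describe{
#'   \item{t}{0-based time-frame index.}
#'   \item{s}{0-based z-slice index.}
#'   \item{cx, cy}{box center in continuous pixel units, 0-based, x rightward,
#'     y downward.}
#'   \item{w, h}{box width and height in pixels (> 0).}
#'   \item{p}{confidence in [0, 1]; 1 for ground truth.}
#'   \item{event_id}{integer linking the boxes of one mitotic event across
#'     slices and frames (ground truth only; NA for detections).}
#' }
#' Box extents are half-open intervals: a box covers
#' \code{[cx - w/2, cx + w/2) x [cy - h/2, cy + h/2)}.
#'
#' @param t,s integer frame and slice indices (0-based).
#' @param cx,cy,w,h box geometry in pixels.
#' @param p confidence scores in [0, 1].
#' @param event_id optional integer event labels (NA for detections).
#' @return A \code{data.frame} of class \code{mito_boxes}.
#' @examples
#' boxes(t = 0, s = 2, cx = 10, cy = 12, w = 8, h = 6, p = 1, event_id = 1L)
#' @export
boxes <- function(t = integer(), s = integer(), cx = numeric(), cy = numeric(),
                  w = numeric(), h = numeric(), p = numeric(),
                  event_id = NA_integer_) {
  n <- max(length(cx), length(cy), length(w), length(h))
  df <- data.frame(t = as.integer(rep_len(t, n)), s = as.integer(rep_len(s, n)),
                   cx = as.numeric(rep_len(cx, n)), cy = as.numeric(rep_len(cy, n)),
                   w = as.numeric(rep_len(w, n)), h = as.numeric(rep_len(h, n)),
                   p = as.numeric(rep_len(p, n)),
                   event_id = as.integer(rep_len(event_id, n)))
  if (n == 0) {
    df <- data.frame(t = integer(), s = integer(), cx = numeric(),
                     cy = numeric(), w = numeric(), h = numeric(),
                     p = numeric(), event_id = integer())
  }
  validate_boxes(df)
}

#' @rdname boxes
#' @param x a data frame with the box columns.
#' @export
as_boxes <- function(x) {
  cols <- c("t", "s", "cx", "cy", "w", "h", "p")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0)
    stop("box table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"event_id" %in% names(x)) x$event_id <- NA_integer_
  df <- data.frame(t = as.integer(x$t), s = as.integer(x$s),
                   cx = as.numeric(x$cx), cy = as.numeric(x$cy),
                   w = as.numeric(x$w), h = as.numeric(x$h),
                   p = as.numeric(x$p), event_id = as.integer(x$event_id))
  validate_boxes(df)
}

validate_boxes <- function(df) {
  if (nrow(df) > 0) {
    if (any(!is.finite(df$w)) || any(!is.finite(df$h)) ||
        any(df$w <= 0) || any(df$h <= 0))
      stop("box widths and heights must be finite and > 0")
    if (any(!is.finite(df$p)) || any(df$p < 0) || any(df$p > 1))
      stop("box confidences must lie in [0, 1]")
    if (any(df$t < 0, na.rm = TRUE) || any(df$s < 0, na.rm = TRUE))
      stop("frame and slice indices are 0-based and must be >= 0")
  }
  class(df) <- c("mito_boxes", "data.frame")
  df
}

empty_boxes <- function() boxes()

#' Convert between center and corner box parameterisations
#'
#' @param b a box table (or any data frame with cx, cy, w, h).
#' @return \code{box_corners}: a data frame with columns x1, y1, x2, y2
#'   (half-open extents, \code{x1 = cx - w/2}, \code{x2 = cx + w/2}).
#' @export
box_corners <- function(b) {
  data.frame(x1 = b$cx - b$w / 2, y1 = b$cy - b$h / 2,
             x2 = b$cx + b$w / 2, y2 = b$cy + b$h / 2)
}

#' @rdname box_corners
#' @param x1,y1,x2,y2 corner coordinates with \code{x2 > x1}, \code{y2 > y1}.
#' @return \code{box_from_corners}: a data frame with cx, cy, w, h.
#' @export
box_from_corners <- function(x1, y1, x2, y2) {
  data.frame(cx = (x1 + x2) / 2, cy = (y1 + y2) / 2, w = x2 - x1, h = y2 - y1)
}

#' Planar intersection-over-union between boxes
#'
#' IoU is computed on the (x, y) plane only; slice and frame indices are
#' ignored. Cross-slice agreement is the business of the 4D refinement and the
#' 4D evaluation protocol, which operate on per-slice planar boxes.
#'
#' @param a,b single-row box tables (or lists with cx, cy, w, h).
#' @return a scalar in [0, 1]; 1 for identical extents, 0 for disjoint boxes.
#' @examples
#' b1 <- boxes(0, 0, cx = 2, cy = 2, w = 4, h = 4, p = 1)
#' b2 <- boxes(0, 0, cx = 4, cy = 4, w = 4, h = 4, p = 1)
#' box_iou(b1, b2)  # 4/28
#' @export
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$cx + a$w / 2, b$cx + b$w / 2) -
                  pmax(a$cx - a$w / 2, b$cx - b$w / 2))
  iy <- pmax(0, pmin(a$cy + a$h / 2, b$cy + b$h / 2) -
                  pmax(a$cy - a$h / 2, b$cy - b$h / 2))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

#' IoU matrix between two box tables
#'
#' @param a,b box tables with na and nb rows.
#' @return an na x nb matrix of planar IoU values.
#' @export
box_iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(0, na, nb))
  ax1 <- a$cx - a$w / 2; ax2 <- a$cx + a$w / 2
  ay1 <- a$cy - a$h / 2; ay2 <- a$cy + a$h / 2
  bx1 <- b$cx - b$w / 2; bx2 <- b$cx + b$w / 2
  by1 <- b$cy - b$h / 2; by2 <- b$cy + b$h / 2
  ix <- pmax(0, outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax))
  iy <- pmax(0, outer(ay2, by2, pmin) - outer(ay1, by1, pmax))
  inter <- ix * iy
  union <- outer(a$w * a$h, b$w * b$h, `+`) - inter
  inter / union
}

#' Greedy confidence-ordered box matching
#'
#' Candidates are visited in order of decreasing confidence \code{p} (ties
#' broken lexicographically on cx, cy, w, h for full determinism); each
#' candidate claims the still-unclaimed reference with the highest IoU, if
#' that IoU reaches \code{iou_min}. Each reference is matched at most once.
#'
#' @param candidates box table of detections at one (t, s) context.
#' @param references box table of reference (ground-truth) boxes at the same
#'   context.
#' @param iou_min minimum IoU for a pairing.
#' @param strict if TRUE the IoU must strictly exceed \code{iou_min}
#'   (the 2D evaluation protocol's "exceeded" reading); if FALSE (default)
#'   \code{>=} is used.
#' @return a list with \code{match}: integer vector over candidate rows giving
#'   the matched reference row (NA if unmatched), and \code{iou}: the IoU of
#'   each pairing (NA if unmatched).
#' @export
greedy_match <- function(candidates, references, iou_min, strict = FALSE) {
  nc <- nrow(candidates); nr <- nrow(references)
  match <- rep(NA_integer_, nc)
  miou <- rep(NA_real_, nc)
  if (nc == 0 || nr == 0) return(list(match = match, iou = miou))
  ord <- order(-candidates$p, candidates$cx, candidates$cy,
               candidates$w, candidates$h)
  iou <- box_iou_matrix(candidates, references)
  taken <- rep(FALSE, nr)
  for (ci in ord) {
    ious <- iou[ci, ]
    ious[taken] <- -1
    best <- which.max(ious)
    ok <- if (strict) ious[best] > iou_min else ious[best] >= iou_min
    if (length(best) == 1 && ok) {
      match[ci] <- best
      miou[ci] <- ious[best]
      taken[best] <- TRUE
    }
  }
  list(match = match, iou = miou)
}

#' Read and write box tables
#'
#' Box tables serialize as CSV with header \code{t,s,cx,cy,w,h,p,event_id}
#' (event_id empty for detections) or as an equivalent JSON array of objects.
#' Readers accept either format, keyed on the file extension (.csv / .json).
#'
#' @param path file path ending in .csv or .json.
#' @return \code{read_boxes}: a box table.
#' @export
read_boxes <- function(path) {
  if (!file.exists(path)) stop("no such box file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::fromJSON(path)
    if (length(x) == 0) return(empty_boxes())
    x <- as.data.frame(x)
  } else if (ext == "csv") {
    x <- utils::read.csv(path)
  } else {
    stop("box files must be .csv or .json, got: ", path)
  }
  if (nrow(x) == 0) return(empty_boxes())
  as_boxes(x)
}

#' @rdname read_boxes
#' @param b a box table.
#' @export
write_boxes <- function(b, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(b)[, c("t", "s", "cx", "cy", "w", "h", "p", "event_id")]
  if (ext == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA)
  } else if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    stop("box files must be .csv or .json, got: ", path)
  }
  invisible(path)
}

group_key <- function(b) paste(b$t, b$s, sep = ":")

# split a box table by (t, s); returns a named list of sub-tables
split_by_frame_slice <- function(b) {
  if (nrow(b) == 0) return(list())
  split(as.data.frame(b), group_key(b))
}
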