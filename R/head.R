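#' Detection head configuration
#'
#' An anchor-free center-point head: objects are predicted as peaks of a
#' class heatmap at stride 4, with per-cell width/height regression (in input
#' pixels) and a sub-pixel center offset. The head is a function of the fused
#' feature map only, so alternative anchor-free heads can be attached by
#' providing the same \code{forward} contract (heatmap / size / offset maps).
#'
#' @param conv_channels channels of the pre-head 3x3 convolution.
#' @param score_min decode confidence floor for raw detections (the 4D
#'   refinement applies its own 0.5 rule afterwards).
#' @param k_max maximum detections decoded per slice.
#' @param w_heat,w_size,w_offset loss weights of the focal heatmap term and
#'   the two L1 regression terms.
#' @param min_overlap minimum IoU governing the target Gaussian radius.
#' @return a \code{head_config} list.
#' @export
head_config <- function(conv_channels = 32L, score_min = 0.3, k_max = 32L,
                        w_heat = 1.0, w_size = 0.1, w_offset = 1.0,
                        min_overlap = 0.7) {
  structure(list(conv_channels = as.integer(conv_channels),
                 score_min = score_min, k_max = as.integer(k_max),
                 w_heat = w_heat, w_size = w_size, w_offset = w_offset,
                 min_overlap = min_overlap, stride = 4L),
            class = "head_config")
}

head_init <- function(store, in_channels, config, prefix = "hd") {
  cc <- config$conv_channels
  param_add(store, paste0(prefix, ".conv.w"), init_conv_w(3, 3, in_channels, cc))
  param_add(store, paste0(prefix, ".conv.b"), numeric(cc))
  param_add(store, paste0(prefix, ".hm.w"), init_conv_w(1, 1, cc, 1))
  # bias the heatmap towards background at init so the focal loss starts sane
  param_add(store, paste0(prefix, ".hm.b"), -2.19)
  param_add(store, paste0(prefix, ".size.w"), init_conv_w(1, 1, cc, 2))
  param_add(store, paste0(prefix, ".size.b"), numeric(2))
  param_add(store, paste0(prefix, ".off.w"), init_conv_w(1, 1, cc, 2))
  param_add(store, paste0(prefix, ".off.b"), numeric(2))
  invisible(store)
}

head_forward <- function(tp, fused, config, prefix = "hd") {
  h <- op_relu(tp, op_conv(tp, fused, paste0(prefix, ".conv.w"),
                           paste0(prefix, ".conv.b")))
  list(heatmap = op_sigmoid(tp, op_conv(tp, h, paste0(prefix, ".hm.w"),
                                        paste0(prefix, ".hm.b"))),
       size = op_conv(tp, h, paste0(prefix, ".size.w"), paste0(prefix, ".size.b")),
       offset = op_conv(tp, h, paste0(prefix, ".off.w"), paste0(prefix, ".off.b")))
}

# CornerNet/CenterNet Gaussian radius such that corners displaced by r still
# give IoU >= min_overlap with the annotated box (sizes in feature cells)
gaussian_radius <- function(height, width, min_overlap = 0.7) {
  a1 <- 1; b1 <- height + width
  c1 <- width * height * (1 - min_overlap) / (1 + min_overlap)
  r1 <- (b1 - sqrt(b1^2 - 4 * a1 * c1)) / (2 * a1)
  a2 <- 4; b2 <- 2 * (height + width)
  c2 <- (1 - min_overlap) * width * height
  r2 <- (b2 - sqrt(b2^2 - 4 * a2 * c2)) / (2 * a2)
  a3 <- 4 * min_overlap; b3 <- -2 * min_overlap * (height + width)
  c3 <- (min_overlap - 1) * width * height
  r3 <- (b3 + sqrt(b3^2 - 4 * a3 * c3)) / (2 * a3)
  min(r1, r2, r3)
}

#' Render center-point training targets for one slice
#'
#' Each annotation contributes a Gaussian splat on the stride-4 heatmap
#' (peak value exactly 1 at the integer center cell; overlapping splats are
#' combined by elementwise max) plus width/height (input pixels) and
#' sub-pixel offset targets written at the peak cell.
#'
#' @param ann box table for one (t, s) context.
#' @param map_shape c(H/4, W/4) heatmap shape.
#' @param config a \code{\link{head_config}}.
#' @return a list with \code{heatmap} (H/4 x W/4), \code{size} and
#'   \code{offset} ((H/4) x (W/4) x 2) and logical \code{mask} of peak
#'   cells; attribute \code{skipped} counts boxes whose center fell outside
#'   the map.
#' @export
render_targets <- function(ann, map_shape, config = head_config()) {
  Hm <- map_shape[1]; Wm <- map_shape[2]
  heat <- matrix(0, Hm, Wm)
  size <- array(0, c(Hm, Wm, 2))
  offset <- array(0, c(Hm, Wm, 2))
  mask <- matrix(FALSE, Hm, Wm)
  skipped <- 0L
  stride <- config$stride
  for (r in seq_len(nrow(ann))) {
    cxf <- ann$cx[r] / stride; cyf <- ann$cy[r] / stride
    px <- floor(cxf); py <- floor(cyf)  # 0-based cell indices
    if (px < 0 || px >= Wm || py < 0 || py >= Hm) {
      skipped <- skipped + 1L
      next
    }
    rad <- gaussian_radius(ceiling(ann$h[r] / stride),
                           ceiling(ann$w[r] / stride), config$min_overlap)
    # floor to whole cells but keep at least one cell of soft context:
    # a bare single-cell peak gives the focal loss no tolerance region
    rad <- max(1L, floor(max(0, rad)))
    sigma <- (2 * rad + 1) / 6
    ys <- max(0, py - rad):min(Hm - 1, py + rad)
    xs <- max(0, px - rad):min(Wm - 1, px + rad)
    g <- outer(exp(-(ys - py)^2 / (2 * sigma^2)),
               exp(-(xs - px)^2 / (2 * sigma^2)))
    heat[ys + 1, xs + 1] <- pmax(heat[ys + 1, xs + 1], g)
    heat[py + 1, px + 1] <- 1
    size[py + 1, px + 1, ] <- c(ann$w[r], ann$h[r])
    offset[py + 1, px + 1, ] <- c(cxf - px, cyf - py)
    mask[py + 1, px + 1] <- TRUE
  }
  structure(list(heatmap = heat, size = size, offset = offset, mask = mask),
            skipped = skipped)
}

#' Detection loss
#'
#' Penalty-reduced focal loss on the heatmap plus L1 losses on size and
#' offset evaluated at ground-truth peak cells only, as a weighted sum.
#' Slices without annotations contribute only the background focal term.
#'
#' @param tp a tape.
#' @param pred head output (tape nodes heatmap/size/offset).
#' @param target rendered targets from \code{\link{render_targets}}.
#' @param config a \code{\link{head_config}}.
#' @return a scalar tape node; its value carries attribute \code{components}.
#' @keywords internal
detection_loss <- function(tp, pred, target, config = head_config()) {
  hm_t <- array(target$heatmap, c(dim(target$heatmap), 1))
  l_heat <- op_focal_loss(tp, pred$heatmap, hm_t)
  l_size <- op_l1_masked(tp, pred$size, target$size, target$mask)
  l_off <- op_l1_masked(tp, pred$offset, target$offset, target$mask)
  total <- op_weighted_sum(tp, list(l_heat, l_size, l_off),
                           c(config$w_heat, config$w_size, config$w_offset))
  total$components <- c(heat = l_heat$v, size = l_size$v, offset = l_off$v)
  total
}

# 3x3-neighbourhood local maxima of a matrix (ties count as maxima)
local_maxima_3x3 <- function(hm) {
  Hm <- nrow(hm); Wm <- ncol(hm)
  pad <- matrix(-Inf, Hm + 2, Wm + 2)
  pad[2:(Hm + 1), 2:(Wm + 1)] <- hm
  nbr_max <- matrix(-Inf, Hm, Wm)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nbr_max <- pmax(nbr_max, pad[2:(Hm + 1) + dy, 2:(Wm + 1) + dx])
  }
  hm >= nbr_max
}

#' Decode head outputs into a detection box table
#'
#' Peaks are 3x3-neighbourhood local maxima of the activated heatmap; the
#' top \code{k_max} peaks with score >= \code{score_min} become boxes with
#' \code{cx = stride * (px + offset_x)}, sizes read from the size map, and
#' \code{p} = the heatmap score.
#'
#' @param pred list with plain arrays \code{heatmap} (H/4 x W/4 x 1 or
#'   matrix), \code{size}, \code{offset}.
#' @param t,s frame/slice indices stamped on the output boxes.
#' @param config a \code{\link{head_config}}.
#' @return a box table (possibly empty).
#' @export
decode_detections <- function(pred, t, s, config = head_config()) {
  hm <- pred$heatmap
  if (length(dim(hm)) == 3) hm <- hm[, , 1]
  keep <- local_maxima_3x3(hm) & hm >= config$score_min
  if (!any(keep)) return(empty_boxes())
  idx <- which(keep, arr.ind = TRUE)
  scores <- hm[keep]
  ord <- order(-scores, idx[, 1], idx[, 2])
  ord <- ord[seq_len(min(length(ord), config$k_max))]
  idx <- idx[ord, , drop = FALSE]
  scores <- scores[ord]
  py <- idx[, 1] - 1; px <- idx[, 2] - 1
  n <- length(scores)
  offx <- vapply(seq_len(n), function(k) pred$offset[idx[k, 1], idx[k, 2], 1],
                 numeric(1))
  offy <- vapply(seq_len(n), function(k) pred$offset[idx[k, 1], idx[k, 2], 2],
                 numeric(1))
  w <- vapply(seq_len(n), function(k) pred$size[idx[k, 1], idx[k, 2], 1],
              numeric(1))
  h <- vapply(seq_len(n), function(k) pred$size[idx[k, 1], idx[k, 2], 2],
              numeric(1))
  ok <- w > 0 & h > 0
  if (!any(ok)) return(empty_boxes())
  boxes(t = t, s = s, cx = config$stride * (px + offx)[ok],
        cy = config$stride * (py + offy)[ok], w = w[ok], h = h[ok],
        p = pmin(pmax(scores[ok], 0), 1))
}
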