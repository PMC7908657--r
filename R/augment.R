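#' Augmentation specification and draws
#'
#' Training-time augmentation samples a rotation in [-rotation_max_deg,
#' +rotation_max_deg], an isotropic scale in \code{scale_range}, independent
#' horizontal/vertical flip coin-flips, and (optionally) a random crop.
#' The same sampled draw is applied to every frame of a temporal window so
#' that the window stays geometrically consistent; boxes are transformed by
#' the same affine map and re-tightened to their axis-aligned extent.
#' The default multiplier regime (sampling fresh draws per iteration for the
#' whole training run) realizes a more-than-100-fold expansion of the
#' original data without materializing it.
#'
#' @param rotation_max_deg rotation bound in degrees (sampled uniformly).
#' @param scale_range (min, max) isotropic scale factors.
#' @param flip_horizontal,flip_vertical enable the respective coin-flips.
#' @param crop_fraction linear crop fraction in (0, 1]; 1 disables cropping.
#'   Crop sizes snap down to a multiple of 32 so cropped windows remain
#'   network-compatible.
#' @return an \code{augment_spec} list.
#' @export
augment_spec <- function(rotation_max_deg = 15, scale_range = c(0.8, 1.2),
                         flip_horizontal = TRUE, flip_vertical = TRUE,
                         crop_fraction = 1.0) {
  if (scale_range[1] <= 0 || scale_range[1] > scale_range[2])
    stop("scale_range must be positive with min <= max")
  if (crop_fraction <= 0 || crop_fraction > 1)
    stop("crop_fraction must lie in (0, 1]")
  structure(list(rotation_max_deg = rotation_max_deg,
                 scale_range = scale_range,
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical),
                 crop_fraction = crop_fraction),
            class = "augment_spec")
}

#' @rdname augment_spec
#' @param spec an \code{augment_spec}.
#' @param height,width image size the draw will be applied to.
#' @return \code{augment_draw}: a concrete sampled transform (rotation
#'   degrees, scale, flips, crop origin/size); \code{identity_draw}: the
#'   do-nothing draw.
#' @export
augment_draw <- function(spec, height, width) {
  rot <- stats::runif(1, -spec$rotation_max_deg, spec$rotation_max_deg)
  sc <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
  fh <- spec$flip_horizontal && stats::runif(1) < 0.5
  fv <- spec$flip_vertical && stats::runif(1) < 0.5
  ch <- height; cw <- width; oy <- 0L; ox <- 0L
  if (spec$crop_fraction < 1) {
    ch <- max(32L, 32L * (floor(spec$crop_fraction * height) %/% 32L))
    cw <- max(32L, 32L * (floor(spec$crop_fraction * width) %/% 32L))
    ch <- min(ch, height); cw <- min(cw, width)
    oy <- sample.int(height - ch + 1L, 1) - 1L
    ox <- sample.int(width - cw + 1L, 1) - 1L
  }
  list(rotation_deg = rot, scale = sc, flip_h = fh, flip_v = fv,
       crop = c(oy = oy, ox = ox, h = ch, w = cw))
}

#' @rdname augment_spec
#' @export
identity_draw <- function(height, width) {
  list(rotation_deg = 0, scale = 1, flip_h = FALSE, flip_v = FALSE,
       crop = c(oy = 0L, ox = 0L, h = height, w = width))
}

# forward affine map of continuous (x, y) coordinates (rows of a 2-col
# matrix) about the image center, before cropping
draw_affine <- function(draw, height, width) {
  th <- draw$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Fm <- diag(c(if (draw$flip_h) -1 else 1, if (draw$flip_v) -1 else 1))
  M <- draw$scale * R %*% Fm
  c0 <- c(width / 2, height / 2)
  list(M = M, Minv = solve(M), c0 = c0)
}

#' Apply an augmentation draw to a 2.5D stack and its boxes
#'
#' The image is resampled by inverse bilinear mapping with replicated edges;
#' boxes map their four corners through the same forward affine and are
#' re-tightened to the axis-aligned bounding extent. Boxes whose center
#' leaves the crop are dropped (the count is returned).
#'
#' @param stack (H, W, C) array.
#' @param ann box table in the stack's coordinates.
#' @param draw a draw from \code{\link{augment_draw}}.
#' @return list(stack, ann, dropped).
#' @export
augment_apply <- function(stack, ann, draw) {
  H <- dim(stack)[1]; W <- dim(stack)[2]; C <- dim(stack)[3]
  aff <- draw_affine(draw, H, W)
  cr <- draw$crop
  Ho <- cr[["h"]]; Wo <- cr[["w"]]
  # output pixel centers -> source continuous coords (inverse map)
  gx <- (seq_len(Wo) - 0.5) + cr[["ox"]]
  gy <- (seq_len(Ho) - 0.5) + cr[["oy"]]
  pts <- cbind(rep(gx, each = Ho) - aff$c0[1], rep(gy, times = Wo) - aff$c0[2])
  src <- pts %*% t(aff$Minv)
  sx <- matrix(src[, 1] + aff$c0[1] - 0.5, Ho, Wo)
  sy <- matrix(src[, 2] + aff$c0[2] - 0.5, Ho, Wo)
  x0 <- pmin(pmax(floor(sx), 0), W - 1); x1 <- pmin(x0 + 1, W - 1)
  y0 <- pmin(pmax(floor(sy), 0), H - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- pmin(pmax(sx - x0, 0), 1); fy <- pmin(pmax(sy - y0, 0), 1)
  out <- array(0, c(Ho, Wo, C))
  for (ci in seq_len(C)) {
    ch <- stack[, , ci]
    i00 <- ch[cbind(as.vector(y0) + 1, as.vector(x0) + 1)]
    i01 <- ch[cbind(as.vector(y0) + 1, as.vector(x1) + 1)]
    i10 <- ch[cbind(as.vector(y1) + 1, as.vector(x0) + 1)]
    i11 <- ch[cbind(as.vector(y1) + 1, as.vector(x1) + 1)]
    vfx <- as.vector(fx); vfy <- as.vector(fy)
    out[, , ci] <- matrix(
      (1 - vfy) * ((1 - vfx) * i00 + vfx * i01) +
        vfy * ((1 - vfx) * i10 + vfx * i11), Ho, Wo)
  }
  dropped <- 0L
  new_ann <- ann
  if (nrow(ann) > 0) {
    rows <- lapply(seq_len(nrow(ann)), function(r) {
      b <- ann[r, ]
      corners <- cbind(
        c(b$cx - b$w / 2, b$cx + b$w / 2, b$cx - b$w / 2, b$cx + b$w / 2),
        c(b$cy - b$h / 2, b$cy - b$h / 2, b$cy + b$h / 2, b$cy + b$h / 2))
      tc <- sweep(corners, 2, aff$c0) %*% t(aff$M)
      tc <- sweep(tc, 2, aff$c0, `+`)
      tc[, 1] <- tc[, 1] - cr[["ox"]]
      tc[, 2] <- tc[, 2] - cr[["oy"]]
      bb <- box_from_corners(min(tc[, 1]), min(tc[, 2]),
                             max(tc[, 1]), max(tc[, 2]))
      if (bb$cx < 0 || bb$cx >= Wo || bb$cy < 0 || bb$cy >= Ho) return(NULL)
      b$cx <- bb$cx; b$cy <- bb$cy; b$w <- bb$w; b$h <- bb$h
      b
    })
    keep <- !vapply(rows, is.null, logical(1))
    dropped <- sum(!keep)
    new_ann <- if (any(keep)) validate_boxes(do.call(rbind, rows[keep]))
               else empty_boxes()
  }
  list(stack = out, ann = new_ann, dropped = dropped)
}
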