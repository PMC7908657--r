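#' Temporal aggregation configuration
#'
#' The recurrent stage runs the shared-weight backbone over a temporal window
#' of 2.5D stacks (default seven frames: three before and three after the
#' center frame), aggregates each backbone scale with an independent
#' bidirectional convolutional LSTM, and fuses the per-scale temporal
#' features into one scale-4 map via x2 bilinear upsampling and 1x1
#' convolutions with dense reuse of already-fused scales.
#'
#' @param temporal_span window length in frames (odd; default 7).
#' @param slice_span slices per 2.5D stack (odd; default 3).
#' @param hidden_per_scale convolutional LSTM hidden channels per scale.
#' @param proj_channels channels of each fused per-scale projection; the
#'   fused map carries \code{3 * proj_channels} channels.
#' @return a \code{temporal_config} list.
#' @export
temporal_config <- function(temporal_span = 7L, slice_span = 3L,
                            hidden_per_scale = 8L, proj_channels = 8L) {
  temporal_span <- as.integer(temporal_span)
  slice_span <- as.integer(slice_span)
  if (temporal_span < 1 || temporal_span %% 2 == 0)
    stop("temporal_span must be an odd positive integer")
  if (slice_span < 1 || slice_span %% 2 == 0)
    stop("slice_span must be an odd positive integer")
  structure(list(temporal_span = temporal_span, slice_span = slice_span,
                 hidden_per_scale = as.integer(hidden_per_scale),
                 proj_channels = as.integer(proj_channels)),
            class = "temporal_config")
}

#' Extract a temporal window of 2.5D stacks from a 4D volume
#'
#' For target frame \code{t} and slice \code{s} (both 0-based), returns the
#' stacks of frames \code{t - k .. t + k} (k = half the temporal span); each
#' stack holds slices \code{s - 1, s, s + 1} (for slice span 3) as channels.
#' Indices falling outside the volume are edge-replicated in both time and z,
#' so border windows see repeated boundary frames/slices rather than
#' fabricated dark ones.
#'
#' @param volume a \code{mito_volume4d}.
#' @param t,s 0-based frame and slice index of the window center.
#' @param config a \code{\link{temporal_config}}.
#' @return a list with \code{frames} (list of (H, W, slice_span) arrays),
#'   \code{frame_index} (0-based source frame of each stack), \code{center}
#'   (1-based index of the center stack), and \code{t}, \code{s}.
#' @export
extract_window <- function(volume, t, s, config = temporal_config()) {
  d <- dim(volume$data)
  TT <- d[1]; S <- d[2]; H <- d[3]; W <- d[4]
  if (t < 0 || t >= TT || s < 0 || s >= S)
    stop("window center (t=", t, ", s=", s, ") outside the volume")
  ht <- config$temporal_span %/% 2L
  hs <- config$slice_span %/% 2L
  ts <- pmin(pmax((t - ht):(t + ht), 0L), TT - 1L)
  ss <- pmin(pmax((s - hs):(s + hs), 0L), S - 1L)
  frames <- lapply(ts, function(tf) {
    stack <- array(0, c(H, W, config$slice_span))
    for (k in seq_along(ss)) stack[, , k] <- volume$data[tf + 1, ss[k] + 1, , ]
    stack
  })
  list(frames = frames, frame_index = as.integer(ts), center = ht + 1L,
       t = as.integer(t), s = as.integer(s))
}

# parameters of the bidirectional CLSTMs and the fusion projections
temporal_init <- function(store, bb_config, t_config, prefix = "tmp") {
  Hc <- t_config$hidden_per_scale
  scales <- c(4L, 8L, 16L)
  for (sc in scales) {
    ci <- bb_config$channels_per_level[as.integer(log2(sc / 4)) + 1L]
    for (dir in c("f", "b")) {
      key <- paste0(prefix, ".cl", sc, ".", dir)
      param_add(store, paste0(key, ".w"), init_conv_w(3, 3, ci + Hc, 4L * Hc))
      b <- numeric(4L * Hc)
      b[Hc + seq_len(Hc)] <- 1  # forget-gate bias init
      param_add(store, paste0(key, ".b"), b)
    }
  }
  # fusion order: coarsest first; each projection sees the upsampled CLSTM
  # output (2 Hc channels) plus all previously fused projections
  for (k in seq_along(scales)) {
    cin <- 2L * Hc + (k - 1L) * t_config$proj_channels
    key <- paste0(prefix, ".fuse", rev(scales)[k])
    param_add(store, paste0(key, ".w"),
              init_conv_w(1, 1, cin, t_config$proj_channels))
    param_add(store, paste0(key, ".b"), numeric(t_config$proj_channels))
  }
  invisible(store)
}

clstm_cell <- function(tp, x, h, c, wname, bname, Hc) {
  z <- op_conv(tp, op_concat(tp, list(x, h)), wname, bname)
  i <- op_sigmoid(tp, op_slice_ch(tp, z, 1L, Hc))
  f <- op_sigmoid(tp, op_slice_ch(tp, z, Hc + 1L, 2L * Hc))
  o <- op_sigmoid(tp, op_slice_ch(tp, z, 2L * Hc + 1L, 3L * Hc))
  g <- op_tanh(tp, op_slice_ch(tp, z, 3L * Hc + 1L, 4L * Hc))
  c2 <- op_add(tp, op_mul(tp, f, c), op_mul(tp, i, g))
  h2 <- op_mul(tp, o, op_tanh(tp, c2))
  list(h = h2, c = c2)
}

# run one direction of a CLSTM over a list of tape nodes; returns the state
# after the last element
clstm_run <- function(tp, xs, wname, bname, Hc) {
  d <- dim(xs[[1]]$v)
  h <- op_input(tp, array(0, c(d[1], d[2], Hc)))
  c <- op_input(tp, array(0, c(d[1], d[2], Hc)))
  for (x in xs) {
    st <- clstm_cell(tp, x, h, c, wname, bname, Hc)
    h <- st$h; c <- st$c
  }
  h
}

#' Aggregate per-frame backbone features with bidirectional CLSTMs
#'
#' For each scale independently, a forward CLSTM consumes the stacks up to
#' and including the center frame and a backward CLSTM consumes the stacks
#' from the end down to the center; the two center-step hidden states are
#' concatenated. Spatial sizes are unchanged.
#'
#' @param tp a tape.
#' @param per_frame list (length = temporal span) of per-frame feature lists
#'   keyed by scale ("4", "8", "16"), as returned by the backbone.
#' @param center 1-based index of the center frame.
#' @param t_config a \code{\link{temporal_config}}.
#' @param prefix parameter name prefix.
#' @return a list of tape nodes keyed by scale, each with 2*hidden channels.
#' @keywords internal
clstm_aggregate <- function(tp, per_frame, center, t_config, prefix = "tmp") {
  Hc <- t_config$hidden_per_scale
  out <- list()
  for (sc in c("4", "8", "16")) {
    xs <- lapply(per_frame, function(f) f[[sc]])
    d0 <- dim(xs[[1]]$v)
    for (x in xs) if (!identical(dim(x$v), d0))
      stop("per-frame features disagree in shape at scale ", sc)
    fwd <- clstm_run(tp, xs[seq_len(center)],
                     paste0(prefix, ".cl", sc, ".f.w"),
                     paste0(prefix, ".cl", sc, ".f.b"), Hc)
    bwd <- clstm_run(tp, rev(xs)[seq_len(length(xs) - center + 1L)],
                     paste0(prefix, ".cl", sc, ".b.w"),
                     paste0(prefix, ".cl", sc, ".b.b"), Hc)
    out[[sc]] <- op_concat(tp, list(fwd, bwd))
  }
  out
}

#' Fuse per-scale temporal features into one scale-4 map
#'
#' Coarsest scale first: each scale's temporal features are upsampled to
#' scale 4 (repeated x2 bilinear steps), concatenated with every previously
#' fused projection, and passed through a 1x1 convolution + ReLU. The fused
#' output concatenates the three projections, so its channel count is the
#' sum of the per-scale projection widths.
#'
#' @inheritParams clstm_aggregate
#' @param temporal list of tape nodes keyed by scale ("4", "8", "16").
#' @return one tape node at scale 4 with \code{3 * proj_channels} channels.
#' @keywords internal
fuse_scales <- function(tp, temporal, t_config, prefix = "tmp") {
  for (sc in c("4", "8", "16"))
    if (is.null(temporal[[sc]]))
      stop("fuse_scales: missing temporal features at scale ", sc)
  fused <- list()
  for (sc in c(16L, 8L, 4L)) {
    x <- temporal[[as.character(sc)]]
    ups <- as.integer(log2(sc / 4))
    for (k in seq_len(ups)) x <- op_upsample2x(tp, x)
    inp <- if (length(fused) == 0) x else op_concat(tp, c(list(x), fused))
    key <- paste0(prefix, ".fuse", sc)
    fused[[length(fused) + 1]] <-
      op_relu(tp, op_conv(tp, inp, paste0(key, ".w"), paste0(key, ".b")))
  }
  op_concat(tp, fused)
}
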