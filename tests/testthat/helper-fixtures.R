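# shared fixtures: tiny configs and scene specs sized for CPU test runs

tiny_detector_config <- function() {
  detector_config(
    backbone = backbone_config(I = 3, channels_per_level = c(4L, 6L, 8L)),
    temporal = temporal_config(hidden_per_scale = 4L, proj_channels = 4L),
    head = head_config(conv_channels = 8L))
}

# ---- the end-to-end training profile ---------------------------------------
# Scenes keep cells at data-like absolute size (half-max radius 5.5-6.5 px)
# and shrink only the field of view; events persist over 12 of 16 frames and
# span most of the 10-slice stack, mirroring the persistence structure the
# (N = 4, T = 6) refinement window was designed around.
small_scene_spec <- function(seed, n_events = 1L, n_frames = 16L) {
  scene_spec(height = 64, width = 64, n_slices = 10, n_frames = n_frames,
             n_normal_cells = 5, n_mitotic_events = n_events,
             cell_radius_range = c(5.5, 6.5), mitosis_duration = 12,
             seed = seed)
}

e2e_detector_config <- function() {
  detector_config(
    backbone = backbone_config(I = 3, channels_per_level = c(12L, 18L, 24L)),
    temporal = temporal_config(hidden_per_scale = 8L, proj_channels = 8L),
    head = head_config(conv_channels = 24L, w_heat = 2, w_size = 0.5))
}

e2e_train_config <- function(iterations = 2000L, seed = 1L) {
  train_config("test", lr_initial = 1e-3, lr_final = 1e-4, crop_size = 32L,
               head_lr_mult = 4, batch_size = 2L,
               iterations = iterations, seed = seed)
}

# rotation-free augmentation for the e2e profile: re-tightening rotated
# boxes inflates the axis-aligned size targets by up to ~26% at 15 degrees,
# which biases the size head high and sinks IoU at the strict 0.6 bar;
# flips and scaling cover the orientation and radius variation instead
e2e_augment_spec <- function() {
  augment_spec(rotation_max_deg = 0, scale_range = c(0.8, 1.2))
}

# random valid box table for property tests
random_boxes <- function(n, t = 0L, s = 0L, extent = 50) {
  boxes(t = t, s = s,
        cx = stats::runif(n, 0, extent), cy = stats::runif(n, 0, extent),
        w = stats::runif(n, 0.5, 12), h = stats::runif(n, 0.5, 12),
        p = stats::runif(n))
}

# independent pixel-rasterization IoU oracle on a fine subgrid
raster_iou <- function(a, b, step = 0.05) {
  x1 <- min(a$cx - a$w / 2, b$cx - b$w / 2)
  x2 <- max(a$cx + a$w / 2, b$cx + b$w / 2)
  y1 <- min(a$cy - a$h / 2, b$cy - b$h / 2)
  y2 <- max(a$cy + a$h / 2, b$cy + b$h / 2)
  gx <- seq(x1 + step / 2, x2, by = step)
  gy <- seq(y1 + step / 2, y2, by = step)
  ina <- outer(gy >= a$cy - a$h / 2 & gy < a$cy + a$h / 2,
               gx >= a$cx - a$w / 2 & gx < a$cx + a$w / 2, `&`)
  inb <- outer(gy >= b$cy - b$h / 2 & gy < b$cy + b$h / 2,
               gx >= b$cx - b$w / 2 & gx < b$cx + b$w / 2, `&`)
  sum(ina & inb) / sum(ina | inb)
}

# independent brute-force refinement score: explicit double loop over the
# neighbourhood cells present in the contribution map
brute_refine_score <- function(contrib, N, T) {
  num <- 0; den <- 0
  for (r in seq_len(nrow(contrib))) {
    j <- contrib$j[r]; k <- contrib$k[r]
    w <- 1 - sqrt(j^2 + k^2) / sqrt(N^2 + T^2)
    num <- num + w * contrib$p_hat[r]
    den <- den + w
  }
  if (den <= 0) contrib$p_hat[contrib$j == 0 & contrib$k == 0][1]
  else num / den
}
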