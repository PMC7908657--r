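test_that("target rendering places exactly one unit peak per box", {
  cfg <- head_config()
  ann <- boxes(0, 0, cx = 18, cy = 26, w = 8, h = 8, p = 1)
  tg <- render_targets(ann, c(16, 16), cfg)
  expect_equal(sum(tg$heatmap == 1), 1)
  expect_equal(which(tg$heatmap == 1, arr.ind = TRUE)[1, ],
               c(row = 7, col = 5))  # cell (py=6, px=4), 1-based storage
  expect_equal(tg$size[7, 5, ], c(8, 8))
  expect_equal(tg$offset[7, 5, ], c(0.5, 0.5))
  expect_true(all(tg$heatmap >= 0 & tg$heatmap <= 1))
  # empty annotations: all-zero maps
  tg0 <- render_targets(boxes(), c(16, 16), cfg)
  expect_true(all(tg0$heatmap == 0) && all(tg0$size == 0) &&
                !any(tg0$mask))
  # duplicated boxes collapse under the max combination
  tg2 <- render_targets(rbind(ann, ann), c(16, 16), cfg)
  expect_equal(tg2$heatmap, tg$heatmap)
  expect_equal(tg2$size, tg$size)
  # out-of-map centers are skipped and counted
  far <- boxes(0, 0, cx = 200, cy = 10, w = 4, h = 4, p = 1)
  tg3 <- render_targets(far, c(16, 16), cfg)
  expect_equal(attr(tg3, "skipped"), 1L)
})

test_that("decode inverts the center-point arithmetic", {
  cfg <- head_config(score_min = 0.3)
  hm <- array(0, c(16, 16, 1))
  hm[6, 5, 1] <- 1  # cell (py=5, px=4) 0-based
  size <- array(0, c(16, 16, 2)); size[, , 1] <- 8; size[, , 2] <- 12
  off <- array(0, c(16, 16, 2))
  det <- decode_detections(list(heatmap = hm, size = size, offset = off),
                           t = 2, s = 3, cfg)
  expect_equal(nrow(det), 1)
  expect_equal(det$cx, 16); expect_equal(det$cy, 20)
  expect_equal(det$w, 8); expect_equal(det$h, 12)
  expect_equal(det$p, 1); expect_equal(det$t, 2L); expect_equal(det$s, 3L)
  # all-zero heatmap: empty result
  expect_equal(nrow(decode_detections(
    list(heatmap = array(0, c(16, 16, 1)), size = size, offset = off),
    0, 0, cfg)), 0)
})

test_that("decoded peaks equal a brute-force local-maximum scan", {
  set.seed(19)
  cfg <- head_config(score_min = 0.2, k_max = 100L)
  hm <- array(stats::runif(12 * 12), c(12, 12, 1))
  size <- array(2, c(12, 12, 2))
  off <- array(0, c(12, 12, 2))
  det <- decode_detections(list(heatmap = hm, size = size, offset = off),
                           0, 0, cfg)
  # exhaustive scan: a cell is a peak iff >= all 8 neighbours
  peaks <- list()
  for (y in 1:12) for (x in 1:12) {
    v <- hm[y, x, 1]
    ok <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= 12 && xx >= 1 && xx <= 12 &&
          hm[yy, xx, 1] > v) ok <- FALSE
    }
    if (ok && v >= cfg$score_min)
      peaks[[length(peaks) + 1]] <- c(x - 1, y - 1, v)
  }
  oracle <- do.call(rbind, peaks)
  oracle <- oracle[order(-oracle[, 3]), , drop = FALSE]
  expect_equal(nrow(det), nrow(oracle))
  expect_equal(det$p, oracle[, 3])
  expect_equal(det$cx, 4 * oracle[, 1])
  expect_equal(det$cy, 4 * oracle[, 2])
  expect_true(all(det$p >= cfg$score_min))
  expect_lte(nrow(det), cfg$k_max)
})

test_that("decoding rendered targets recovers the annotations", {
  set.seed(77)
  cfg <- head_config(score_min = 0.99)
  for (rep in 1:10) {
    n <- sample(1:3, 1)
    cells <- cbind(sample(seq(2, 13, by = 3), n), sample(seq(2, 13, by = 3), n))
    ann <- boxes(0, 0,
                 cx = 4 * cells[, 1] + stats::runif(n, 0, 3.9),
                 cy = 4 * cells[, 2] + stats::runif(n, 0, 3.9),
                 w = stats::runif(n, 5, 14), h = stats::runif(n, 5, 14), p = 1)
    tg <- render_targets(ann, c(16, 16), cfg)
    det <- decode_detections(list(heatmap = array(tg$heatmap, c(16, 16, 1)),
                                  size = tg$size, offset = tg$offset),
                             0, 0, cfg)
    m <- greedy_match(det, ann, iou_min = 0.5)
    expect_equal(sum(!is.na(m$match)), nrow(ann))
    for (ci in which(!is.na(m$match))) {
      ai <- m$match[ci]
      expect_lte(abs(det$cx[ci] - ann$cx[ai]), 0.5)
      expect_lte(abs(det$cy[ci] - ann$cy[ai]), 0.5)
      expect_equal(det$w[ci], ann$w[ai])
      expect_equal(det$h[ci], ann$h[ai])
    }
  }
})

test_that("the detection loss behaves at its limits and under a step", {
  cfg <- head_config()
  params <- mitodetect:::nn_params()
  ann <- boxes(0, 0, cx = 20, cy = 24, w = 8, h = 6, p = 1)
  tg <- render_targets(ann, c(16, 16), cfg)
  # perfect prediction (peak confidence -> 1, background -> 0): loss
  # vanishes in the limit
  tp <- mitodetect:::nn_tape(params, grad = FALSE)
  hm_bin <- array(as.numeric(tg$heatmap == 1), c(16, 16, 1))
  pred <- list(heatmap = mitodetect:::op_input(tp, hm_bin),
               size = mitodetect:::op_input(tp, tg$size),
               offset = mitodetect:::op_input(tp, tg$offset))
  l <- mitodetect:::detection_loss(tp, pred, tg, cfg)
  expect_lt(l$v, 1e-4)
  # random prediction: strictly positive
  set.seed(4)
  pred2 <- list(heatmap = mitodetect:::op_input(tp, array(stats::runif(256), c(16, 16, 1))),
                size = mitodetect:::op_input(tp, array(stats::rnorm(512), c(16, 16, 2))),
                offset = mitodetect:::op_input(tp, array(stats::rnorm(512), c(16, 16, 2))))
  l2 <- mitodetect:::detection_loss(tp, pred2, tg, cfg)
  expect_gt(l2$v, 0)
  # one Adam step on a fixed tiny batch decreases the loss
  m <- detector_init(tiny_detector_config(), seed = 5)
  win <- list(frames = lapply(1:7, function(i) array(0.3, c(32, 32, 3))),
              center = 4L)
  tg2 <- render_targets(boxes(0, 0, cx = 14, cy = 18, w = 8, h = 8, p = 1),
                        c(8, 8), m$config$head)
  fwd <- detector_forward(m, win, grad = TRUE)
  l3 <- mitodetect:::detection_loss(fwd$tape, fwd$pred, tg2, m$config$head)
  pg <- mitodetect:::nn_backward(fwd$tape, l3)
  mitodetect:::adam_step(m$params, pg, 1e-3)
  fwd2 <- detector_forward(m, win, grad = TRUE)
  l4 <- mitodetect:::detection_loss(fwd2$tape, fwd2$pred, tg2, m$config$head)
  expect_lt(l4$v, l3$v)
})
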