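test_that("composite scores reproduce the published convention", {
  expect_equal(round(composite_score(0.0411, 0.7221, "mean"), 4), 0.3816)
  expect_equal(round(composite_score(0.7883, 0.7751, "mean"), 4), 0.7817)
  # P = R = x gives x under either convention
  for (x in c(0, 0.25, 0.7, 1)) {
    expect_equal(composite_score(x, x, "mean"), x)
    expect_equal(composite_score(x, x, "harmonic"), x)
  }
  expect_equal(composite_score(0, 0, "harmonic"), 0)
  expect_equal(composite_score(0.5, 1, "harmonic"), 2 * 0.5 / 1.5)
  expect_error(composite_score(1.2, 0.5, "mean"))
})

test_that("2D evaluation counts confusion cases like a hand tally", {
  ann <- boxes(t = c(0, 0, 1), s = c(0, 0, 0), cx = c(10, 30, 10),
               cy = c(10, 30, 10), w = 6, h = 6, p = 1)
  # identical detections: perfect scores
  det <- ann; det$p <- 0.9
  r <- evaluate_2d(det, ann)
  expect_equal(c(r$tp, r$fp, r$fn), c(3L, 0L, 0L))
  expect_equal(r$precision, 1); expect_equal(r$recall, 1)
  expect_equal(r$score_mean, 1); expect_equal(r$score_harmonic, 1)
  # no detections: degenerate zeros
  r0 <- evaluate_2d(boxes(), ann)
  expect_equal(c(r0$precision, r0$recall, r0$score_mean), c(0, 0, 0))
  # 2 TP, 1 FP, 1 FN by construction
  det2 <- rbind(
    boxes(0, 0, cx = 10, cy = 10, w = 6, h = 6, p = 0.9),   # TP
    boxes(0, 0, cx = 30.5, cy = 30, w = 6, h = 6, p = 0.8), # TP (IoU ~ 0.85)
    boxes(0, 0, cx = 50, cy = 50, w = 6, h = 6, p = 0.7))   # FP
  r2 <- evaluate_2d(as_boxes(det2), ann)                     # (1,0,10,10) FN
  expect_equal(c(r2$tp, r2$fp, r2$fn), c(2L, 1L, 1L))
  expect_equal(r2$precision, 2 / 3)
  expect_equal(r2$recall, 2 / 3)
  expect_equal(r2$score_mean, 2 / 3)
})

test_that("the 0.6 threshold is strict, per the protocol's 'exceeded'", {
  ann <- boxes(0, 0, cx = 10, cy = 10, w = 10, h = 10, p = 1)
  # a box with IoU exactly 0.6: 10x10 overlapped by 10x6... use 6/10 ratio:
  # same center, w=10, h=6: inter 60, union 100 -> IoU 0.6 exactly
  det_eq <- boxes(0, 0, cx = 10, cy = 10, w = 10, h = 6, p = 0.9)
  expect_equal(evaluate_2d(det_eq, ann)$tp, 0L)
  det_gt <- boxes(0, 0, cx = 10, cy = 10, w = 10, h = 6.2, p = 0.9)
  expect_equal(evaluate_2d(det_gt, ann)$tp, 1L)
})

test_that("2D counts partition detections and annotations", {
  set.seed(15)
  for (rep in 1:10) {
    det <- random_boxes(sample(0:8, 1), t = sample(0:1, 1), s = 0L)
    ann <- random_boxes(sample(0:6, 1), t = sample(0:1, 1), s = 0L)
    if (nrow(ann) > 0) ann$p <- 1
    r <- evaluate_2d(det, ann)
    expect_equal(r$tp + r$fp, nrow(det))
    expect_equal(r$tp + r$fn, nrow(ann))
  }
})

# one event's ground truth: identical centered boxes on a slice range
event_gt <- function(t, slices, id, cx = 20, cy = 20, w = 10, h = 10) {
  do.call(rbind, lapply(slices, function(s)
    boxes(t = t, s = s, cx = cx, cy = cy, w = w, h = h, p = 1, event_id = id)))
}

test_that("4D evaluation credits events by 5-slice average IoU runs", {
  # perfect detection of a 6-slice event: 1 TP
  ann <- as_boxes(event_gt(0, 0:5, 1))
  det <- ann; det$p <- 0.9; det$event_id <- NA_integer_
  r <- evaluate_4d(det, ann)
  expect_equal(c(r$tp, r$fn, r$fp), c(1L, 0L, 0L))
  # an event spanning only 3 slices cannot be credited: FN + flagged
  ann3 <- as_boxes(event_gt(0, 0:2, 7))
  det3 <- ann3; det3$p <- 0.9; det3$event_id <- NA_integer_
  r3 <- evaluate_4d(det3, ann3)
  expect_equal(c(r3$tp, r3$fn, r3$fp), c(0L, 1L, 0L))
  expect_equal(r3$short_events, 7L)
})

test_that("4D evaluation matches the hand-derived alternating-IoU case", {
  # 7-slice event; detections alternate IoU 0.8 / 0.6 against it
  ann <- as_boxes(event_gt(2, 0:6, 1))
  det_ev <- do.call(rbind, lapply(0:6, function(s) {
    h <- if (s %% 2 == 0) 8 else 6  # 10x8 -> IoU 0.8; 10x6 -> IoU 0.6
    boxes(t = 2, s = s, cx = 20, cy = 20, w = 10, h = h, p = 0.9)
  }))
  # spurious self-consistent 5-slice stack elsewhere
  det_fp <- do.call(rbind, lapply(1:5, function(s)
    boxes(t = 2, s = s, cx = 45, cy = 45, w = 8, h = 8, p = 0.8)))
  det <- as_boxes(rbind(det_ev, det_fp))
  r <- evaluate_4d(det, ann)
  # hand check: any 5-slice window mean IoU is (3*0.8+2*0.6)/5 = 0.72 or
  # (2*0.8+3*0.6)/5 = 0.68, both > 0.5 -> TP; the stack at (45,45) has
  # self-IoU 1 over 5 slices and no ground truth -> 1 FP
  expect_equal(c(r$tp, r$fn, r$fp), c(1L, 0L, 1L))
  # detection ordering must not matter
  perm <- det[sample(nrow(det)), ]
  r2 <- evaluate_4d(as_boxes(perm), ann)
  expect_equal(c(r2$tp, r2$fn, r2$fp), c(1L, 0L, 1L))
})

test_that("a persistent FP stack counts once across frames", {
  ann <- as_boxes(event_gt(0, 0:5, 1))
  det_ev <- ann; det_ev$p <- 0.9; det_ev$event_id <- NA_integer_
  det_fp <- do.call(rbind, lapply(0:3, function(t)
    do.call(rbind, lapply(1:5, function(s)
      boxes(t = t, s = s, cx = 45, cy = 45, w = 8, h = 8, p = 0.8)))))
  r <- evaluate_4d(as_boxes(rbind(det_ev, det_fp)), ann)
  expect_equal(r$tp, 1L)
  expect_equal(r$fp, 1L)
})
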