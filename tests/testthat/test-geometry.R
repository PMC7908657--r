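test_that("corner/center conversion follows the half-open convention", {
  b <- boxes(0, 0, cx = 2, cy = 2, w = 4, h = 4, p = 1)
  expect_equal(unlist(box_corners(b)), c(x1 = 0, y1 = 0, x2 = 4, y2 = 4))
  b2 <- boxes(0, 0, cx = 0, cy = 0, w = 2, h = 2, p = 1)
  expect_equal(unlist(box_corners(b2)), c(x1 = -1, y1 = -1, x2 = 1, y2 = 1))
  # round-trip corners -> center -> corners is the identity
  set.seed(11)
  rb <- random_boxes(50)
  cc <- box_corners(rb)
  back <- box_from_corners(cc$x1, cc$y1, cc$x2, cc$y2)
  expect_equal(back$cx, rb$cx)
  expect_equal(back$cy, rb$cy)
  expect_equal(back$w, rb$w)
  expect_equal(back$h, rb$h)
})

test_that("box tables validate their invariants", {
  expect_error(boxes(0, 0, cx = 1, cy = 1, w = 0, h = 2, p = 1), "widths")
  expect_error(boxes(0, 0, cx = 1, cy = 1, w = 2, h = 2, p = 1.2), "confidences")
  expect_error(boxes(-1, 0, cx = 1, cy = 1, w = 2, h = 2, p = 1), "0-based")
  expect_equal(nrow(boxes()), 0)
})

test_that("planar IoU matches identity, disjoint and rasterization oracles", {
  a <- boxes(0, 0, cx = 2, cy = 2, w = 4, h = 4, p = 1)
  expect_equal(box_iou(a, a), 1.0)
  far <- boxes(0, 0, cx = 102, cy = 2, w = 4, h = 4, p = 1)
  expect_equal(box_iou(a, far), 0.0)
  b <- boxes(0, 0, cx = 4, cy = 4, w = 4, h = 4, p = 1)
  expect_equal(box_iou(a, b), 4 / 28)
  # fine-subgrid pixel counting converges to the analytic value
  expect_equal(raster_iou(a, b), 4 / 28, tolerance = 1e-2)
  set.seed(21)
  for (i in 1:20) {
    x <- random_boxes(1, extent = 10)
    y <- random_boxes(1, extent = 10)
    expect_lt(abs(box_iou(x, y) - raster_iou(x, y)), 0.015)
  }
})

test_that("IoU is symmetric, bounded and consistent with the matrix form", {
  set.seed(7)
  a <- random_boxes(1000)
  b <- random_boxes(1000)
  iab <- box_iou(a, b)
  iba <- box_iou(b, a)
  expect_equal(iab, iba)
  expect_true(all(iab >= 0 & iab <= 1))
  expect_equal(box_iou(a, a), rep(1, 1000))
  m <- box_iou_matrix(a[1:5, ], b[1:4, ])
  for (i in 1:5) for (j in 1:4)
    expect_equal(m[i, j], box_iou(a[i, ], b[j, ]))
})

# independent greedy oracle: naive loops + rasterized IoU
greedy_oracle <- function(cand, ref, iou_min) {
  ord <- order(-cand$p, cand$cx, cand$cy, cand$w, cand$h)
  taken <- rep(FALSE, nrow(ref))
  match <- rep(NA_integer_, nrow(cand))
  for (ci in ord) {
    best <- NA_integer_; best_iou <- -1
    for (ri in seq_len(nrow(ref))) {
      if (taken[ri]) next
      v <- raster_iou(cand[ci, ], ref[ri, ], step = 0.02)
      if (v > best_iou) { best_iou <- v; best <- ri }
    }
    if (!is.na(best) && best_iou >= iou_min - 1e-3) {
      match[ci] <- best; taken[best] <- TRUE
    }
  }
  match
}

test_that("greedy matching is deterministic and agrees with a brute-force oracle", {
  ref <- boxes(0, 0, cx = 5, cy = 5, w = 4, h = 4, p = 1)
  hit <- boxes(0, 0, cx = 5, cy = 5, w = 4, h = 4, p = 0.9)
  m <- greedy_match(hit, ref, iou_min = 0.6)
  expect_equal(m$match, 1L)
  expect_equal(greedy_match(boxes(), ref, 0.6)$match, integer(0))
  m0 <- greedy_match(boxes(), ref, 0.6)
  expect_true(all(is.na(m0$match)) || length(m0$match) == 0)

  # constructed overlap grids vs the oracle (integer-aligned boxes so the
  # rasterized oracle IoU is exact)
  set.seed(5)
  for (rep in 1:8) {
    cand <- boxes(0, 0, cx = sample(3:9, 3, TRUE), cy = sample(3:9, 3, TRUE),
                  w = sample(2:6, 3, TRUE), h = sample(2:6, 3, TRUE),
                  p = round(stats::runif(3), 2))
    ref <- boxes(0, 0, cx = sample(3:9, 2, TRUE), cy = sample(3:9, 2, TRUE),
                 w = sample(2:6, 2, TRUE), h = sample(2:6, 2, TRUE), p = 1)
    got <- greedy_match(cand, ref, iou_min = 0.3)
    expect_equal(got$match, greedy_oracle(cand, ref, 0.3))
  }
})

test_that("greedy matching never pairs below the threshold", {
  set.seed(13)
  for (rep in 1:25) {
    cand <- random_boxes(sample(0:6, 1), extent = 15)
    ref <- random_boxes(sample(0:5, 1), extent = 15)
    m <- greedy_match(cand, ref, iou_min = 0.4)
    expect_true(all(m$iou[!is.na(m$match)] >= 0.4))
    expect_lte(sum(!is.na(m$match)), min(nrow(cand), nrow(ref)))
    # each reference claimed at most once
    expect_false(any(duplicated(stats::na.omit(m$match))))
  }
})

test_that("box tables round-trip through CSV and JSON", {
  b <- boxes(t = c(0, 0, 3), s = c(1, 2, 5), cx = c(10.5, 20.25, 3),
             cy = c(4, 8.75, 9), w = c(5, 6, 7), h = c(5, 4, 3),
             p = c(1, 0.625, 0.25), event_id = c(1L, 1L, NA))
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_boxes(b, csv)
  write_boxes(b, json)
  expect_equal(as.data.frame(read_boxes(csv)), as.data.frame(b))
  expect_equal(as.data.frame(read_boxes(json)), as.data.frame(b))
  expect_error(read_boxes(tempfile(fileext = ".csv")), "no such")
  expect_error(write_boxes(b, tempfile(fileext = ".txt")), "csv or .json")
})
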