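test_that("confidence binarization is inclusive at the threshold", {
  expect_equal(binarize(0.5), 1)
  expect_equal(binarize(0.49), 0)
  expect_equal(binarize(1.0), 1)
  expect_equal(binarize(0.0), 0)
  expect_equal(binarize(c(0.2, 0.5, 0.8)), c(0, 1, 1))
  expect_error(binarize(1.2))
})

test_that("neighbour weights follow the normalized euclidean distance", {
  expect_equal(neighbour_weight(0, 0, 4, 6), 1.0)
  expect_equal(neighbour_weight(4, 6, 4, 6), 0.0)
  expect_equal(neighbour_weight(3, 4, 4, 6), 1 - 5 / sqrt(52))
  expect_error(neighbour_weight(5, 0, 4, 6), "offsets")
  expect_error(neighbour_weight(0, 7, 4, 6), "offsets")
  # symmetry and monotone decay over the full N=4, T=6 grid
  for (j in 0:4) for (k in 0:6) {
    w <- neighbour_weight(j, k, 4, 6)
    expect_equal(w, neighbour_weight(-j, k, 4, 6))
    expect_equal(w, neighbour_weight(j, -k, 4, 6))
    expect_true(w >= 0 && w <= 1)
    if (j > 0) expect_lte(w, neighbour_weight(j - 1, k, 4, 6))
    if (k > 0) expect_lte(w, neighbour_weight(j, k - 1, 4, 6))
  }
})

test_that("refined scores equal the brute-force double sum", {
  cfg <- refinement_config()
  full <- expand.grid(j = -4:4, k = -6:6)
  ones <- cbind(full, p_hat = 1)
  zeros <- cbind(full, p_hat = 0)
  expect_equal(refine_score(ones, cfg), 1.0)
  expect_equal(refine_score(zeros, cfg), 0.0)
  # the worked 3x3 grid at N = T = 1
  cfg1 <- refinement_config(N = 1, T = 1)
  grid <- expand.grid(j = -1:1, k = -1:1)
  grid$p_hat <- 0
  grid$p_hat[grid$j <= 0 & grid$k <= 0] <- 1  # [[1,1,0],[1,1,0],[0,0,0]]
  expect_equal(refine_score(grid, cfg1), brute_refine_score(grid, 1, 1))
  # random contribution maps, including truncated windows
  set.seed(101)
  for (i in 1:120) {
    keep <- sort(sample(nrow(full), sample(30:nrow(full), 1)))
    sub <- full[keep, ]
    if (!any(sub$j == 0 & sub$k == 0)) sub <- rbind(sub, c(0, 0))
    sub$p_hat <- stats::rbinom(nrow(sub), 1, 0.4)
    got <- refine_score(sub, cfg)
    want <- brute_refine_score(sub, 4, 6)
    expect_lte(abs(got - want) / max(1e-12, abs(want)), 1e-12)
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("adding an agreeing neighbour never decreases the refined score", {
  set.seed(55)
  cfg <- refinement_config()
  full <- expand.grid(j = -4:4, k = -6:6)
  for (i in 1:30) {
    full$p_hat <- stats::rbinom(nrow(full), 1, 0.3)
    zero_rows <- which(full$p_hat == 0 & !(full$j == 0 & full$k == 0))
    if (length(zero_rows) == 0) next
    base <- refine_score(full, cfg)
    flip <- full
    flip$p_hat[sample(zero_rows, 1)] <- 1
    expect_gte(refine_score(flip, cfg), base)
  }
})

test_that("neighbour association fills the contribution map correctly", {
  cfg <- refinement_config(N = 1, T = 1)
  target <- boxes(t = 1, s = 1, cx = 10, cy = 10, w = 6, h = 6, p = 0.9)
  # identical copies everywhere: all contributions 1
  det_all <- do.call(rbind, lapply(0:2, function(t)
    do.call(rbind, lapply(0:2, function(s)
      boxes(t = t, s = s, cx = 10, cy = 10, w = 6, h = 6, p = 0.9)))))
  ca <- associate_neighbours(target, as_boxes(det_all), 3, 3, cfg)
  expect_equal(nrow(ca), 9)
  expect_true(all(ca$p_hat == 1))
  # only the target exists: (0,0) contributes its own binarized p
  cb <- associate_neighbours(target, target, 3, 3, cfg)
  expect_equal(cb$p_hat[cb$j == 0 & cb$k == 0], 1)
  expect_true(all(cb$p_hat[!(cb$j == 0 & cb$k == 0)] == 0))
  # constructed 3-slice, 3-frame toy with planted matches: hand enumeration
  det <- rbind(
    boxes(t = 1, s = 1, cx = 10, cy = 10, w = 6, h = 6, p = 0.9),  # target
    boxes(t = 0, s = 1, cx = 10.5, cy = 10, w = 6, h = 6, p = 0.8),# match
    boxes(t = 2, s = 1, cx = 10, cy = 10, w = 6, h = 6, p = 0.3),  # low p
    boxes(t = 1, s = 0, cx = 11, cy = 11, w = 6, h = 6, p = 0.7),  # match
    boxes(t = 1, s = 2, cx = 30, cy = 30, w = 6, h = 6, p = 0.9),  # far away
    boxes(t = 0, s = 0, cx = 10, cy = 10, w = 6, h = 6, p = 1.0))  # diagonal
  cc <- associate_neighbours(target, as_boxes(det), 3, 3, cfg)
  want <- c("-1:-1" = 1,  # (j=-1, k=-1): t=0, s=0 copy, p=1 -> 1
            "0:-1" = 1,   # t=0, s=1 shifted copy, p=0.8 -> 1
            "1:-1" = 0,   # no detection at t=0, s=2
            "-1:0" = 1,   # t=1, s=0, IoU ~ 0.64, p=0.7 -> 1
            "0:0" = 1,    # the target itself
            "1:0" = 0,    # t=1, s=2 far box: IoU 0 -> no association
            "-1:1" = 0, "0:1" = 0,
            "1:1" = 0)    # t=2, s=1 has p=0.3 -> binarized 0
  got <- stats::setNames(cc$p_hat, paste(cc$j, cc$k, sep = ":"))
  expect_equal(got[names(want)], want)
})

test_that("refinement suppresses isolated boxes and keeps persistent ones", {
  cfg <- refinement_config()
  S <- 10; TT <- 20
  # persistent event: same box at slices 2..6, frames 5..14
  persistent <- do.call(rbind, lapply(5:14, function(t)
    do.call(rbind, lapply(2:6, function(s)
      boxes(t = t, s = s, cx = 20, cy = 20, w = 8, h = 8, p = 0.9)))))
  lone <- boxes(t = 9, s = 8, cx = 50, cy = 50, w = 8, h = 8, p = 0.95)
  det <- as_boxes(rbind(persistent, lone))
  out <- refine(det, n_slices = S, n_frames = TT, cfg, keep = FALSE)
  lone_row <- out[out$cx == 50, ]
  # brute-force expectation for the isolated box: only (0,0) agrees, full
  # in-volume window in the denominator
  num <- 0; den <- 0
  for (j in -4:4) for (k in -6:6) {
    if (9 + k < 0 || 9 + k >= TT || 8 + j < 0 || 8 + j >= S) next
    w <- 1 - sqrt(j^2 + k^2) / sqrt(4^2 + 6^2)
    den <- den + w
    if (j == 0 && k == 0) num <- num + w
  }
  expect_equal(lone_row$p_refined, num / den, tolerance = 1e-12)
  expect_lt(lone_row$p_refined, cfg$keep_threshold)
  # the interior persistent boxes stay above the keep threshold (the event
  # spans 5 of the 9 slices and 10 of the 13 frames of the window, so the
  # weighted agreement is well below 1 but comfortably above 0.5)
  mid <- out[out$t == 9 & out$s == 4 & out$cx == 20, ]
  expect_gt(mid$p_refined, cfg$keep_threshold)
  kept <- refine(det, n_slices = S, n_frames = TT, cfg)
  expect_false(any(kept$cx == 50))
  expect_true(all(kept$p_refined >= cfg$keep_threshold))
  expect_true(all(c("p_hat", "p_refined") %in% names(kept)))
  # geometry unchanged for surviving boxes
  expect_true(all(kept$w == 8 & kept$h == 8))
  # empty input -> empty output
  expect_equal(nrow(refine(boxes(), 4, 4, cfg)), 0)
})

test_that("refinement configs validate their domain", {
  expect_error(refinement_config(N = 0, T = 0), "not both 0")
  expect_error(refinement_config(keep_threshold = 0), "thresholds")
  expect_error(refinement_config(N = -1), "N >= 0")
})
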