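test_that("scene generation is deterministic and event-linked", {
  spec <- small_scene_spec(seed = 4, n_events = 2)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))
  expect_setequal(unique(a$annotations$event_id), c(1L, 2L))
  expect_equal(dim(a$volume$data), c(16, 10, 64, 64))
  expect_true(all(a$volume$data >= 0 & a$volume$data <= 1))
})

test_that("scenes without events yield empty annotations", {
  spec <- small_scene_spec(seed = 9, n_events = 0)
  sc <- generate_scene(spec)
  expect_equal(nrow(sc$annotations), 0)
})

test_that("specs whose events cannot fit are rejected", {
  expect_error(scene_spec(height = 16, width = 16, n_slices = 4, n_frames = 8,
                          n_mitotic_events = 1, cell_radius_range = c(5, 8),
                          mitosis_duration = 4),
               "exceeds the volume")
  expect_error(scene_spec(mitosis_duration = 2), "mitosis_duration")
  expect_error(scene_spec(n_frames = 4, mitosis_duration = 8,
                          height = 64, width = 64),
               "exceeds n_frames")
})

test_that("annotation boxes tightly cover the above-half-maximum event mask", {
  # clean forward model: no normal cells, no blur, no noise, so the event
  # field can be reconstructed from the volume itself (independent oracle)
  spec <- scene_spec(height = 64, width = 64, n_slices = 10, n_frames = 8,
                     n_normal_cells = 0, n_mitotic_events = 1,
                     cell_radius_range = c(4, 5), mitosis_duration = 6,
                     blur_sigma = 0, noise_sd = 0, background_level = 0.1,
                     seed = 31)
  sc <- generate_scene(spec)
  ann <- sc$annotations
  expect_gt(nrow(ann), 0)
  for (t in unique(ann$t)) {
    field <- sc$volume$data[t + 1, , , ] - spec$background_level
    thr <- 0.5 * max(field)
    for (r in which(ann$t == t)) {
      s <- ann$s[r]
      mask <- field[s + 1, , ] >= thr
      expect_gte(sum(mask), 4)
      # coverage: box contains at least 95% of mask pixels in this slice
      px <- which(mask, arr.ind = TRUE)  # (y, x) 1-based
      cx <- ann$cx[r]; cy <- ann$cy[r]; w <- ann$w[r]; h <- ann$h[r]
      inside <- (px[, 2] - 0.5) >= cx - w / 2 & (px[, 2] - 0.5) < cx + w / 2 &
                (px[, 1] - 0.5) >= cy - h / 2 & (px[, 1] - 0.5) < cy + h / 2
      expect_gte(mean(inside), 0.95)
    }
  }
})

test_that("annotation count matches an independent mask-scanning oracle", {
  spec <- scene_spec(height = 64, width = 64, n_slices = 10, n_frames = 8,
                     n_normal_cells = 0, n_mitotic_events = 1,
                     cell_radius_range = c(4, 5), mitosis_duration = 6,
                     blur_sigma = 0, noise_sd = 0, seed = 55)
  sc <- generate_scene(spec)
  oracle_count <- 0L
  for (t in sort(unique(sc$annotations$t))) {
    field <- sc$volume$data[t + 1, , , ] - spec$background_level
    thr <- 0.5 * max(field)
    qual <- which(vapply(seq_len(spec$n_slices),
                         function(s) sum(field[s, , ] >= thr) >= 4, logical(1)))
    s_peak <- which.max(apply(field, 1, max))
    runs <- split(qual, cumsum(c(1, diff(qual) != 1)))
    run <- runs[[which(vapply(runs, function(rn)
      s_peak >= min(rn) && s_peak <= max(rn), logical(1)))[1]]]
    oracle_count <- oracle_count + length(run)
  }
  expect_equal(nrow(sc$annotations), oracle_count)
})

test_that("event boxes occupy contiguous frame and slice ranges", {
  for (seed in c(2, 17, 23)) {
    sc <- generate_scene(small_scene_spec(seed = seed, n_events = 2))
    ann <- sc$annotations
    for (e in unique(ann$event_id)) {
      sub <- ann[ann$event_id == e, ]
      ts <- sort(unique(sub$t))
      expect_equal(ts, seq(min(ts), max(ts)))
      for (t in ts) {
        ss <- sort(sub$s[sub$t == t])
        expect_equal(ss, seq(min(ss), max(ss)))
      }
    }
  }
})

test_that("fixtures round-trip through TIFF + CSV", {
  sc <- generate_scene(scene_spec(height = 32, width = 48, n_slices = 4,
                                  n_frames = 3, n_normal_cells = 3,
                                  n_mitotic_events = 0, seed = 8))
  dir <- file.path(tempdir(), "fixture_rt")
  unlink(dir, recursive = TRUE)
  write_fixture(sc$volume, sc$annotations, dir)
  back <- read_fixture(dir)
  expect_equal(as.data.frame(back$annotations), as.data.frame(sc$annotations))
  # 16-bit quantization bound per voxel
  expect_lte(max(abs(back$volume$data - sc$volume$data)), 1 / 65535)
  expect_equal(dim(back$volume$data), dim(sc$volume$data))
  expect_error(read_fixture(file.path(tempdir(), "nonexistent_fixture")),
               "no scene fixture")
})

test_that("the TIFF codec agrees with an external reader", {
  stack <- array(stats::runif(4 * 20 * 30), c(4, 20, 30))
  path <- tempfile(fileext = ".tif")
  write_tiff(stack, path)
  back <- read_tiff(path)
  expect_equal(dim(back), dim(stack))
  expect_lte(max(abs(back - stack)), 1 / 65535)
  # cross-check against Python tifffile (present in the supported stack):
  # emit the reference values as text in C order (page, y, x) and let Python
  # compare them with what tifffile reads from our file
  py <- Sys.which("python")
  if (nzchar(py)) {
    txt <- tempfile(fileext = ".txt")
    writeLines(format(as.vector(aperm(stack, c(3, 2, 1))), digits = 17), txt)
    script <- sprintf(paste0(
      "import tifffile, numpy as np\n",
      "a = tifffile.imread(%s).astype(float) / 65535.0\n",
      "ref = np.loadtxt(%s).reshape(a.shape)\n",
      "print(a.shape[0], a.shape[1], a.shape[2])\n",
      "print(float(np.abs(a - ref).max()))\n"),
      deparse(path), deparse(txt))
    res <- suppressWarnings(system2(py, c("-c", shQuote(script)),
                                    stdout = TRUE, stderr = TRUE))
    if (is.null(attr(res, "status"))) {
      expect_equal(as.numeric(strsplit(res[1], " ")[[1]]), dim(stack))
      expect_lte(as.numeric(res[2]), 1 / 65535 + 1e-9)
    }
  }
  expect_error(read_tiff(tempfile(fileext = ".tif")), "no such")
  bad <- tempfile(fileext = ".tif")
  writeBin(as.raw(1:20), bad)
  expect_error(read_tiff(bad), "not a little-endian TIFF")
})
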