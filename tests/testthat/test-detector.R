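test_that("a blank neutral image yields no detections", {
  img <- array(rep(c(0.82, 0.82, 0.80), each = 64 * 64), dim = c(64, 64, 3))
  dets <- segment_fruits(img, cfg = calibration_config(px_per_cm = 10))
  expect_equal(nrow(dets), 0L)
})

test_that("noiseless synthetic scenes are detected fruit-for-fruit", {
  sc <- generate_scene(test_scene_spec(n_fruits = 6, seed = 11))
  dets <- segment_fruits(sc$image, cfg = sc$cfg)
  expect_equal(nrow(dets), 6L)
  expect_true(all(dets$confidence == 1))
  # every mask sits inside its box and mask areas track the analytic areas
  expect_true(all(vapply(seq_len(nrow(dets)), function(i) {
    all(dim(dets$mask[[i]]) == c(dets$h[i], dets$w[i]))
  }, logical(1))))
  gt <- sc$ground_truth[order(sc$ground_truth$cx), ]
  dd <- dets[order(dets$x + dets$w / 2), ]
  expect_equal(dd$area_px, gt$area_px, tolerance = 0.02)
})

test_that("specks below the minimum area are filtered out", {
  img <- array(rep(c(0.82, 0.82, 0.80), each = 64 * 64), dim = c(64, 64, 3))
  img[30:31, 30:31, 1] <- 0.8; img[30:31, 30:31, 2] <- 0.1
  img[30:31, 30:31, 3] <- 0.1                       # 4-px speck
  dets <- segment_fruits(img, min_area_px = 50)
  expect_equal(nrow(dets), 0L)
  dets2 <- segment_fruits(img, min_area_px = 2)
  expect_equal(nrow(dets2), 1L)
})

test_that("segmentation is deterministic and rejects non-RGB input", {
  sc <- generate_scene(test_scene_spec(seed = 21))
  d1 <- segment_fruits(sc$image, cfg = sc$cfg)
  d2 <- segment_fruits(sc$image, cfg = sc$cfg)
  expect_identical(d1, d2)
  expect_error(segment_fruits(array(0.5, dim = c(10, 10, 1))), "RGB")
})

test_that("exact prototype colors classify to their own stage", {
  pal <- default_stage_palette()
  for (i in seq_len(nrow(pal))) {
    img <- array(rep(c(pal$r[i], pal$g[i], pal$b[i]), each = 400),
                 dim = c(20, 20, 3))
    det <- tibble::tibble(x = 2, y = 2, w = 10, h = 10)
    expect_equal(as.character(classify_stage(img, det, pal)),
                 as.character(pal$stage[i]))
  }
})

test_that("exact two-prototype ties break toward the lower ripeness ordinal", {
  # palette with two identical prototypes: any region color matching them
  # is equidistant from both, so the lower ordinal must win
  cols <- matrix(c(0.3, 0.5, 0.2,
                   0.7, 0.3, 0.2,
                   0.7, 0.3, 0.2,
                   0.4, 0.1, 0.1), ncol = 3, byrow = TRUE,
                 dimnames = list(stage_levels(), NULL))
  expect_error(stage_palette(cols), "distinct")
  cols["Ripe Pinton", ] <- cols["Ripe Pinton", ] + 1e-3  # barely distinct
  pal <- stage_palette(cols)
  img <- array(rep(c(0.7, 0.3, 0.2), each = 100), dim = c(10, 10, 3))
  det <- tibble::tibble(x = 1, y = 1, w = 8, h = 8)
  expect_equal(as.character(classify_stage(img, det, pal)), "Pinton Green")
})

test_that("classification on masked regions ignores background pixels", {
  pal <- default_stage_palette()
  img <- array(rep(c(0.82, 0.82, 0.80), each = 30 * 30), dim = c(30, 30, 3))
  m <- matrix(FALSE, 10, 10); m[3:8, 3:8] <- TRUE
  for (ch in 1:3) {
    block <- img[11:20, 11:20, ch]
    block[m] <- c(pal$r[4], pal$g[4], pal$b[4])[ch]
    img[11:20, 11:20, ch] <- block
  }
  det <- tibble::tibble(x = 10, y = 10, w = 10, h = 10, mask = list(m))
  expect_equal(as.character(classify_stage(img, det, pal)), "Ripe")
  empty <- tibble::tibble(x = 10, y = 10, w = 10, h = 10,
                          mask = list(matrix(FALSE, 10, 10)))
  expect_error(classify_stage(img, empty, pal), "empty")
})

test_that("PNG round-trip preserves the raster for the detector", {
  sc <- generate_scene(test_scene_spec(n_fruits = 3, seed = 31))
  path <- withr::local_tempfile(fileext = ".png")
  write_scene_png(sc, path)
  img <- read_image(path)
  expect_equal(dim(img), dim(sc$image))
  # 8-bit quantization only
  expect_lt(max(abs(img - sc$image)), 1 / 255)
  dets <- segment_fruits(path, cfg = sc$cfg)
  expect_equal(nrow(dets), 3L)
})
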