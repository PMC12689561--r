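test_that("scene generation is byte-reproducible from its seed", {
  a <- generate_scene(test_scene_spec(seed = 5))
  b <- generate_scene(test_scene_spec(seed = 5))
  expect_identical(a$image, b$image)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_scene(test_scene_spec(seed = 6))
  expect_false(identical(a$image, c$image))
})

test_that("an empty spec renders a blank neutral canvas", {
  sc <- generate_scene(test_scene_spec(n_fruits = 0))
  expect_equal(nrow(sc$ground_truth), 0L)
  expect_true(all(sc$image[, , 1] == 0.82))
  expect_equal(dim(sc$image), c(320, 320, 3))
})

test_that("ground truth carries analytic areas and recomputable expectations", {
  sc <- generate_scene(test_scene_spec(n_fruits = 5, seed = 17))
  gt <- sc$ground_truth
  expect_equal(nrow(gt), 5L)
  expect_equal(gt$area_px, pi * gt$a_px * gt$b_px)
  expect_equal(gt$area_cm2, px_area_to_cm2(gt$area_px, sc$cfg))
  m <- maturity_factor_of(gt$stage, sc$cfg)
  keep <- !is.na(m)
  expect_equal(gt$pulp_g[keep], pulp_from_area(gt$area_cm2[keep], m[keep],
                                               sc$cfg))
  R1 <- sc$cfg$stage_reference_conc[as.character(gt$stage[keep])]
  expect_equal(gt$conc_mg_per_100g[keep],
               unname(R1) * gt$pulp_g[keep] / 100)
  expect_true(all(is.na(gt$pulp_g[!keep])))
  # physical sizes are in the configured diameter range
  d_cm <- 2 * gt$a_px / sc$spec$px_per_cm
  expect_true(all(d_cm >= 2.0 & d_cm <= 3.2))
})

test_that("rasterized fruit areas agree with the analytic ellipse area", {
  sc <- generate_scene(test_scene_spec(n_fruits = 4, seed = 23))
  gt <- sc$ground_truth
  for (i in seq_len(nrow(gt))) {
    rast <- oracle_raster_ellipse_area(gt$cx[i], gt$cy[i], gt$a_px[i],
                                       gt$b_px[i], gt$theta[i], 320)
    expect_lt(abs(rast - gt$area_px[i]) / gt$area_px[i], 0.02)
  }
})

test_that("non-overlap placement is honored and capacity errors are raised", {
  sc <- generate_scene(test_scene_spec(n_fruits = 6, seed = 41))
  gt <- sc$ground_truth
  d <- as.matrix(dist(cbind(gt$cx, gt$cy)))
  r <- gt$a_px
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gt(d[i, j], r[i] + r[j])
  }
  expect_error(
    generate_scene(scene_spec(image_size_px = 256, n_fruits = 40, seed = 1)),
    "capacity"
  )
})

test_that("noise options perturb the render without breaking bounds", {
  sp <- test_scene_spec(n_fruits = 3, seed = 13, gaussian_sigma = 0.05,
                        highlight_prob = 1, blur_sigma = 1.5)
  sc <- generate_scene(sp)
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  clean <- generate_scene(test_scene_spec(n_fruits = 3, seed = 13))
  expect_false(identical(sc$image, clean$image))
})

test_that("added noise never improves staging accuracy on average", {
  acc <- function(sigma) {
    accs <- vapply(1:3, function(s) {
      sc <- generate_scene(test_scene_spec(n_fruits = 5, seed = 50 + s,
                                           gaussian_sigma = sigma))
      dets <- segment_fruits(sc$image, cfg = sc$cfg, sat_threshold = 0.3)
      if (nrow(dets) != 5L) return(0)
      gt <- sc$ground_truth[order(sc$ground_truth$cx), ]
      dd <- dets[order(dets$x + dets$w / 2), ]
      mean(as.character(dd$stage) == as.character(gt$stage))
    }, numeric(1))
    mean(accs)
  }
  a0 <- acc(0); a1 <- acc(0.15); a2 <- acc(0.45)
  expect_gte(a0, a1)
  expect_gte(a1, a2)
})

test_that("ground truth round-trips through COCO annotations", {
  sc <- generate_scene(test_scene_spec(n_fruits = 4, seed = 8))
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sc$ground_truth, js, 320, csv_path = cs)
  back <- load_external_detections(js)
  expect_equal(nrow(back), 4L)
  expect_equal(back$x, sc$ground_truth$x)
  expect_equal(back$w, sc$ground_truth$w)
  expect_equal(as.character(back$stage), as.character(sc$ground_truth$stage))
  csv <- read.csv(cs)
  expect_equal(csv$pulp_g, sc$ground_truth$pulp_g)
})
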