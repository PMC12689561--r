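test_that("the proportional concentration estimator scales by the mass ratio", {
  expect_identical(estimate_concentration(2187.50, 100, 100), 2187.50)
  expect_equal(estimate_concentration(2187.50, 12.30, 100), 269.0625)
  expect_equal(estimate_concentration(2033.32, 0, 100), 0)
  # linear in the estimated mass
  expect_equal(estimate_concentration(1790.37, 2 * 7, 100),
               2 * estimate_concentration(1790.37, 7, 100))
  expect_error(estimate_concentration(2000, 10, 0), "positive")
  expect_error(estimate_concentration(-5, 10, 100), "positive")
})

test_that("per-fruit total ascorbate converts per-100-g units correctly", {
  expect_equal(fruit_total_ascorbate(2187.50, 10), 218.75)
  expect_equal(fruit_total_ascorbate(1234, 0), 0)
  expect_equal(fruit_total_ascorbate(100, 100), 100)
  expect_error(fruit_total_ascorbate(-1, 1), "non-negative")
})

test_that("quantify_fruits builds complete records and excludes Green", {
  det <- tibble::tibble(
    x = c(0, 0), y = c(0, 0), w = c(100, 80), h = c(90, 80),
    confidence = 1, stage = c("Ripe", "Green")
  )
  cfg <- calibration_config(px_per_cm = 50)
  rec <- quantify_fruits(det, cfg)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$excluded, c(FALSE, TRUE))
  expect_true(is.na(rec$pulp_g[2]) && is.na(rec$ascorbate_mg_per_100g[2]))
  A <- (pi * 100 * 90 / 4) / 50^2
  expect_equal(rec$area_cm2[1], A)
  expect_equal(rec$pulp_g[1], pulp_from_area(A, 2, cfg))
  expect_equal(rec$ascorbate_mg_per_100g[1],
               2187.50 * rec$pulp_g[1] / 100)
  expect_equal(rec$ascorbate_total_mg[1], 2187.50 / 100 * rec$pulp_g[1])

  # thickness-density alternative estimator
  rec_t <- quantify_fruits(det, cfg, pulp_model = "thickness")
  expect_equal(rec_t$pulp_g[1], A * 0.8)

  expect_error(quantify_fruits(dplyr::mutate(det, stage = NA)), "stage")
})

test_that("image aggregation sums commercial fruit only", {
  det <- tibble::tibble(
    x = 0, y = 0, w = c(90, 70, 60), h = c(90, 70, 60),
    confidence = 1, stage = c("Ripe", "Ripe", "Green")
  )
  cfg <- calibration_config(px_per_cm = 40)
  rec <- quantify_fruits(det, cfg)
  rep <- aggregate_image(rec, cfg)
  expect_equal(rep$n_fruits, 3L)
  expect_equal(rep$n_excluded, 1L)
  expect_equal(rep$total_pulp_g, sum(rec$pulp_g[1:2]))
  expect_equal(rep$total_area_cm2, sum(rec$area_cm2[1:2]))
  expect_equal(rep$total_ascorbate_mg, sum(rec$ascorbate_total_mg[1:2]))
  ps <- rep$per_stage
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$estimated_mg_per_100g,
               2187.50 * sum(rec$pulp_g[1:2]) / 100)

  # dropping Green records leaves all totals unchanged
  rep2 <- aggregate_image(rec[rec$stage != "Green", ], cfg)
  expect_equal(rep2$total_pulp_g, rep$total_pulp_g)
  expect_equal(rep2$total_ascorbate_mg, rep$total_ascorbate_mg)
  expect_equal(rep2$per_stage$estimated_mg_per_100g,
               ps$estimated_mg_per_100g)

  # permutation invariance
  rep3 <- aggregate_image(rec[c(3, 1, 2), ], cfg)
  expect_equal(rep3$total_pulp_g, rep$total_pulp_g)
  expect_equal(glance(rep3), glance(rep))
})

test_that("an empty record list aggregates to a zero report", {
  rep <- aggregate_image(tibble::tibble())
  expect_equal(rep$n_fruits, 0L)
  expect_equal(rep$total_pulp_g, 0)
  expect_equal(rep$total_ascorbate_mg, 0)
  expect_equal(nrow(rep$per_stage), 0L)
})

test_that("two Ripe fruits of 5 g pulp give the composed stage estimate", {
  rec <- tibble::tibble(
    stage = stage_factor(c("Ripe", "Ripe")),
    area_px = c(1, 1), area_cm2 = c(1, 1), maturity = c(2, 2),
    pulp_g = c(5, 5),
    ascorbate_mg_per_100g = estimate_concentration(2187.5, c(5, 5), 100),
    ascorbate_total_mg = fruit_total_ascorbate(2187.5, c(5, 5)),
    excluded = c(FALSE, FALSE)
  )
  rep <- aggregate_image(rec)
  expect_equal(rep$per_stage$estimated_mg_per_100g, 2187.5 * 10 / 100)
})

test_that("image reports serialize to JSON and flat CSV", {
  det <- tibble::tibble(x = 0, y = 0, w = 50, h = 50, confidence = 1,
                        stage = "Ripe")
  cfg <- calibration_config(px_per_cm = 40)
  rep <- aggregate_image(quantify_fruits(det, cfg), cfg)
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_image_report(rep, json_path = js, csv_path = cs)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$n_fruits, 1L)
  expect_equal(parsed$total_pulp_g, rep$total_pulp_g)
  expect_equal(parsed$schema_version, "1.0")
  flat <- read.csv(cs)
  expect_equal(nrow(flat), 1L)
  expect_equal(flat$pulp_g, rep$records$pulp_g)
})
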