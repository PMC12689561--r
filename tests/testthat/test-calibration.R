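test_that("pixel-to-physical area conversion follows the linear scale", {
  cfg <- calibration_config()
  expect_equal(px_area_to_cm2(143.79^2, cfg), 1.0)
  expect_equal(px_area_to_cm2(0, cfg), 0.0)
  expect_equal(px_area_to_cm2(2 * 143.79^2, cfg), 2.0)
  expect_error(px_area_to_cm2(-1, cfg), "non-negative")
})

test_that("area conversion is homogeneous under joint rescaling of the scale", {
  set.seed(42)
  for (i in 1:10) {
    k <- runif(1, 0.2, 5)
    a <- runif(1, 0, 1e6)
    s <- runif(1, 20, 300)
    base <- px_area_to_cm2(a, calibration_config(px_per_cm = s))
    scaled <- px_area_to_cm2(k^2 * a, calibration_config(px_per_cm = k * s))
    expect_equal(scaled, base)
  }
})

test_that("thickness-density pulp conversion is the stated product and is linear", {
  cfg <- calibration_config()
  expect_equal(pulp_mass_from_thickness(1.0, cfg), 0.8)
  expect_equal(pulp_mass_from_thickness(2.5, cfg), 2.0)
  expect_equal(pulp_mass_from_thickness(0, cfg), 0)
  a <- c(1.3, 0.7); expect_equal(pulp_mass_from_thickness(sum(a), cfg),
                                 sum(pulp_mass_from_thickness(a, cfg)))
  expect_error(pulp_mass_from_thickness(-0.1, cfg), "non-negative")
})

test_that("region area uses mask counts or the inscribed ellipse", {
  det <- tibble::tibble(x = 0, y = 0, w = 100, h = 60, mask = list(NULL))
  expect_equal(region_area_px(det, "ellipse"), pi * 100 * 60 / 4,
               tolerance = 1e-12)
  expect_equal(round(region_area_px(det, "ellipse"), 2), 4712.39)
  det10 <- tibble::tibble(x = 0, y = 0, w = 10, h = 10)
  expect_equal(round(region_area_px(det10, "ellipse"), 2), 78.54)

  m <- matrix(FALSE, 40, 40); m[sample(1600, 500)] <- TRUE
  detm <- tibble::tibble(x = 0, y = 0, w = 40, h = 40, mask = list(m))
  expect_equal(region_area_px(detm, "mask"), 500)
  expect_equal(region_area_px(detm, "auto"), 500)

  # inscribed ellipse never exceeds its box, and rasterization agrees
  # with the closed form within the discretization error
  rast <- oracle_raster_ellipse_area(50, 30, 50, 30, 0, 100)
  expect_lt(abs(rast - pi * 100 * 60 / 4) / (pi * 100 * 60 / 4), 0.02)
  expect_lte(region_area_px(det, "ellipse"), 100 * 60)

  bad <- tibble::tibble(x = 0, y = 0, w = 0, h = 10)
  expect_error(region_area_px(bad), "degenerate")
})

test_that("calibration config validates its physical constants", {
  expect_error(calibration_config(px_per_cm = -1), "positive")
  expect_error(calibration_config(area_class_bounds_cm2 = c(8, 5)),
               "increasing")
  expect_error(calibration_config(stage_reference_conc = c(
    Green = -1, `Pinton Green` = 1, `Ripe Pinton` = 1, Ripe = 1
  )), "positive")
  expect_error(calibration_config(maturity_factor = c(
    `Pinton Green` = 0, `Ripe Pinton` = 1, Ripe = 5
  )), "0, 1, 2")
  # Green never carries a maturity factor
  expect_true(is.na(maturity_factor_of("Green")))
  expect_equal(maturity_factor_of(c("Pinton Green", "Ripe Pinton", "Ripe")),
               c(0, 1, 2))
})

test_that("config files round-trip through YAML and JSON with defaults filled", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("px_per_cm: 100", "pulp_thickness_cm: 0.5"), yml)
  cfg <- read_calibration_config(yml)
  expect_equal(cfg$px_per_cm, 100)
  expect_equal(cfg$pulp_thickness_cm, 0.5)
  expect_equal(cfg$reference_mass_g, 100)        # default retained
  expect_equal(unname(cfg$stage_reference_conc["Ripe"]), 2187.50)

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"px_per_cm": 50, "stage_reference_conc":
    {"Green": 1000, "PintonGreen": 1100, "RipePinton": 1200, "Ripe": 1300}}',
    js)
  cfg2 <- read_calibration_config(js)
  expect_equal(cfg2$px_per_cm, 50)
  expect_equal(unname(cfg2$stage_reference_conc["Pinton Green"]), 1100)

  writeLines("nonsense_field: 3", yml)
  expect_error(read_calibration_config(yml), "unknown config field")
})

test_that("stage labels normalize across the spellings used in the field", {
  expect_equal(as.character(stage_factor("Pinton Ripe")), "Ripe Pinton")
  expect_equal(as.character(stage_factor("Turn-Green")), "Pinton Green")
  expect_equal(stage_ordinal(stage_levels()), 0:3)
  expect_equal(is_commercial_stage(stage_levels()),
               c(FALSE, TRUE, TRUE, TRUE))
  expect_error(stage_factor("banana"), "unknown ripeness stage")
})
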