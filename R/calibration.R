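#' Calibration configuration
#'
#' Bundles every physical and model constant of the estimation pipeline:
#' the linear pixel-to-centimetre scale of the acquisition geometry, the
#' mean pulp thickness and density used by the thickness-density pulp
#' estimator, the certified stage-specific laboratory concentrations and
#' their reference sample mass, the coefficients of the quadratic pulp
#' calibration, and the maturity-factor mapping for commercial stages.
#'
#' The default scale of 143.79 px/cm is valid only for the calibrated
#' capture distance of 30 cm; images taken at another distance need their
#' own `px_per_cm`.
#'
#' @param px_per_cm Linear scale in pixels per centimetre (default 143.79).
#' @param pulp_thickness_cm Mean pulp thickness in cm (default 0.8).
#' @param pulp_density_g_per_cm3 Pulp density in g/cm^3 (default 1).
#' @param reference_mass_g Laboratory reference sample mass b1 in grams
#'   (default 100).
#' @param stage_reference_conc Named numeric: certified ascorbic acid
#'   concentration R1 in mg/100 g for each of the four stages.
#' @param pulp_poly Named numeric `c(a2, a1, a0, aM)`: coefficients of the
#'   pulp model P = a2*A^2 + a1*A + a0 + aM*M (grams, A in cm^2, M in
#'   0/1/2).
#' @param maturity_factor Named integer mapping each commercial stage to its
#'   maturity factor M; Green has none.
#' @param area_class_bounds_cm2 Strictly increasing pair of area-class
#'   boundaries in cm^2 (default `c(5, 8)`), interpreted half-open:
#'   `[0,5)`, `[5,8)`, `[8,Inf)`.
#' @param reference_area_interval_cm2 Reference area interval in cm^2
#'   established from laboratory trials (default 2.5).
#' @return An object of class `camu_calibration` (a validated list).
#' @export
#' @examples
#' cfg <- calibration_config()
#' px_area_to_cm2(143.79^2, cfg)
calibration_config <- function(px_per_cm = 143.79,
                               pulp_thickness_cm = 0.8,
                               pulp_density_g_per_cm3 = 1,
                               reference_mass_g = 100,
                               stage_reference_conc = c(
                                 "Green"        = 1539.40,
                                 "Pinton Green" = 1790.37,
                                 "Ripe Pinton"  = 2033.32,
                                 "Ripe"         = 2187.50
                               ),
                               pulp_poly = c(a2 = 0.084, a1 = -0.252,
                                             a0 = 6.292, aM = 0.63),
                               maturity_factor = c("Pinton Green" = 0,
                                                   "Ripe Pinton"  = 1,
                                                   "Ripe"         = 2),
                               area_class_bounds_cm2 = c(5, 8),
                               reference_area_interval_cm2 = 2.5) {
  cfg <- list(
    px_per_cm = as.numeric(px_per_cm),
    pulp_thickness_cm = as.numeric(pulp_thickness_cm),
    pulp_density_g_per_cm3 = as.numeric(pulp_density_g_per_cm3),
    reference_mass_g = as.numeric(reference_mass_g),
    stage_reference_conc = .named_by_stage(stage_reference_conc,
                                           stage_levels()),
    pulp_poly = pulp_poly,
    maturity_factor = .named_by_stage(maturity_factor, commercial_stages()),
    area_class_bounds_cm2 = as.numeric(area_class_bounds_cm2),
    reference_area_interval_cm2 = as.numeric(reference_area_interval_cm2)
  )
  class(cfg) <- "camu_calibration"
  validate_calibration(cfg)
}

# Normalize the names of a per-stage map and check coverage.
.named_by_stage <- function(x, expected) {
  if (is.null(names(x))) abort("per-stage values must be named by stage")
  names(x) <- as.character(stage_factor(names(x)))
  if (!setequal(names(x), expected)) {
    abort(sprintf("per-stage map must cover exactly: %s",
                  paste(expected, collapse = ", ")))
  }
  x[expected]
}

#' @rdname calibration_config
#' @param cfg A `camu_calibration` object to validate.
#' @export
validate_calibration <- function(cfg) {
  stopifnot(inherits(cfg, "camu_calibration"))
  if (!is.finite(cfg$px_per_cm) || cfg$px_per_cm <= 0)
    abort("px_per_cm must be a positive number")
  for (f in c("pulp_thickness_cm", "pulp_density_g_per_cm3",
              "reference_mass_g", "reference_area_interval_cm2")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      abort(sprintf("%s must be a positive number", f))
  }
  if (any(cfg$stage_reference_conc <= 0))
    abort("stage reference concentrations must be positive")
  if (!all(c("a2", "a1", "a0", "aM") %in% names(cfg$pulp_poly)))
    abort("pulp_poly must name coefficients a2, a1, a0, aM")
  if (!all(cfg$maturity_factor %in% 0:2))
    abort("maturity factors must lie in {0, 1, 2}")
  b <- cfg$area_class_bounds_cm2
  if (length(b) != 2L || !all(is.finite(b)) || diff(b) <= 0 || b[1] <= 0)
    abort("area_class_bounds_cm2 must be two strictly increasing positive numbers")
  cfg
}

#' @export
print.camu_calibration <- function(x, ...) {
  cat("<camu_calibration>\n")
  cat(sprintf("  scale: %.2f px/cm (valid for the calibrated capture distance)\n",
              x$px_per_cm))
  cat(sprintf("  pulp: thickness %.2f cm, density %.2f g/cm^3, reference mass %.0f g\n",
              x$pulp_thickness_cm, x$pulp_density_g_per_cm3,
              x$reference_mass_g))
  cat(sprintf("  pulp model: P = %g A^2 + %g A + %g + %g M\n",
              x$pulp_poly["a2"], x$pulp_poly["a1"], x$pulp_poly["a0"],
              x$pulp_poly["aM"]))
  cat("  reference concentrations (mg/100 g):\n")
  for (s in names(x$stage_reference_conc))
    cat(sprintf("    %-12s %.2f\n", s, x$stage_reference_conc[[s]]))
  invisible(x)
}

#' Read a calibration configuration from YAML or JSON
#'
#' The file mirrors [calibration_config()] field for field; unset fields
#' take the defaults. Per-stage maps (`stage_reference_conc`,
#' `maturity_factor`) may use any spelling accepted by [stage_factor()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `camu_calibration` object.
#' @export
read_calibration_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(sprintf("unsupported config format '.%s' (use YAML or JSON)", ext))
  )
  known <- names(formals(calibration_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    abort(sprintf("unknown config field(s): %s", paste(extra, collapse = ", ")))
  raw <- lapply(raw, function(v) if (is.list(v)) unlist(v) else v)
  do.call(calibration_config, raw)
}

#' Convert a pixel area to a physical area
#'
#' Divides by the squared linear scale: `area_px / px_per_cm^2`.
#'
#' @param area_px Non-negative pixel area(s).
#' @param cfg A [calibration_config()].
#' @return Physical area(s) in cm^2.
#' @export
#' @examples
#' px_area_to_cm2(143.79^2)  # 1 cm^2 by definition of the scale
px_area_to_cm2 <- function(area_px, cfg = calibration_config()) {
  stopifnot(inherits(cfg, "camu_calibration"))
  if (any(!is.finite(area_px)) || any(area_px < 0))
    abort("pixel areas must be finite and non-negative")
  area_px / cfg$px_per_cm^2
}

#' Convert a physical area to pulp mass via thickness and density
#'
#' The projected area is extruded by the mean pulp thickness and multiplied
#' by the pulp density: `area * thickness * density`. This is the simple
#' volumetric alternative to the quadratic calibration [pulp_from_area()].
#'
#' @param area_cm2 Non-negative physical area(s) in cm^2.
#' @param cfg A [calibration_config()].
#' @return Pulp mass(es) in grams.
#' @export
#' @examples
#' pulp_mass_from_thickness(2.5)  # 2 g under the default 0.8 cm x 1 g/cm^3
pulp_mass_from_thickness <- function(area_cm2, cfg = calibration_config()) {
  stopifnot(inherits(cfg, "camu_calibration"))
  if (any(!is.finite(area_cm2)) || any(area_cm2 < 0))
    abort("areas must be finite and non-negative")
  area_cm2 * cfg$pulp_thickness_cm * cfg$pulp_density_g_per_cm3
}

#' Pixel area of detected fruit regions
#'
#' For detections carrying a pixel mask the area is the foreground pixel
#' count. For bare bounding boxes the fruit is approximated by the ellipse
#' inscribed in the box (`pi * w * h / 4`), since camu-camu is near-spherical
#' and a raw box overcounts a round silhouette by 4/pi.
#'
#' @param detections Detection tibble with columns `w`, `h` (positive box
#'   dimensions in px) and optionally a `mask` list-column of logical
#'   matrices.
#' @param shape_model `"auto"` (mask when present, else ellipse), `"mask"`,
#'   or `"ellipse"`.
#' @return Numeric vector of pixel areas, one per detection.
#' @export
region_area_px <- function(detections,
                           shape_model = c("auto", "mask", "ellipse")) {
  shape_model <- match.arg(shape_model)
  stopifnot(is.data.frame(detections), all(c("w", "h") %in% names(detections)))
  if (nrow(detections) == 0L) return(numeric(0))
  if (any(detections$w <= 0) || any(detections$h <= 0))
    abort("degenerate bounding box: w and h must be positive")
  has_mask <- if ("mask" %in% names(detections)) {
    vapply(detections$mask, function(m) !is.null(m), logical(1))
  } else {
    rep(FALSE, nrow(detections))
  }
  if (shape_model == "mask" && !all(has_mask))
    abort("shape_model = \"mask\" requires a mask on every detection")
  use_mask <- switch(shape_model,
    auto    = has_mask,
    mask    = rep(TRUE, nrow(detections)),
    ellipse = rep(FALSE, nrow(detections))
  )
  area <- pi * detections$w * detections$h / 4
  if (any(use_mask)) {
    area[use_mask] <- vapply(detections$mask[use_mask],
                             function(m) sum(m != 0), numeric(1))
  }
  area
}

#' Maturity factor of a stage
#'
#' Commercial stages map to the integer maturity factor M of the pulp model
#' (Pinton Green 0, Ripe Pinton 1, Ripe 2 by default); Green has no maturity
#' factor and maps to `NA`.
#'
#' @param stage Stage names (any spelling accepted by [stage_factor()]).
#' @param cfg A [calibration_config()].
#' @return Numeric vector of maturity factors (`NA` for Green).
#' @export
maturity_factor_of <- function(stage, cfg = calibration_config()) {
  s <- as.character(stage_factor(stage))
  out <- unname(cfg$maturity_factor[s])
  as.numeric(out)
}
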