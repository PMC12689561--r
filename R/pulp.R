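#' Predict pulp mass from projected area and maturity
#'
#' Evaluates the calibrated quadratic pulp model
#' `P = a2*A^2 + a1*A + a0 + aM*M`, where `A` is the projected fruit area in
#' cm^2 and `M` the integer maturity factor (0, 1, or 2 for the commercial
#' stages). Default coefficients come from a manual depulping calibration of
#' 100-g samples across area classes and ripening stages.
#'
#' @param A Non-negative projected area(s) in cm^2.
#' @param M Maturity factor(s) in `{0, 1, 2}`; recycled against `A`.
#' @param cfg A [calibration_config()] supplying `pulp_poly`.
#' @return Predicted pulp mass(es) in grams.
#' @export
#' @examples
#' pulp_from_area(0, 0)   # the model intercept, 6.292 g
#' pulp_from_area(8, 2)
pulp_from_area <- function(A, M, cfg = calibration_config()) {
  stopifnot(inherits(cfg, "camu_calibration"))
  if (any(!is.finite(A)) || any(A < 0))
    abort("projected areas must be finite and non-negative")
  if (any(!is.finite(M)) || !all(M %in% c(0, 1, 2)))
    abort("maturity factor must be 0, 1 or 2")
  p <- cfg$pulp_poly
  p[["a2"]] * A^2 + p[["a1"]] * A + p[["a0"]] + p[["aM"]] * M
}

AREA_CLASSES <- c("less_than_5", "between_5_and_8", "more_than_8")

#' Classify a projected area into the calibration area classes
#'
#' The depulping calibration bins fruit by projected area into three
#' classes. Boundaries are half-open: `[0, b1)`, `[b1, b2)`, `[b2, Inf)`
#' with default bounds 5 and 8 cm^2, so 5.0 falls in the middle class and
#' 8.0 in the top class.
#'
#' @param A Non-negative projected area(s) in cm^2.
#' @param cfg A [calibration_config()] supplying `area_class_bounds_cm2`.
#' @return Factor over `less_than_5`, `between_5_and_8`, `more_than_8`.
#' @export
#' @examples
#' area_class(c(4.2, 5, 8))
area_class <- function(A, cfg = calibration_config()) {
  stopifnot(inherits(cfg, "camu_calibration"))
  if (any(!is.finite(A)) || any(A < 0))
    abort("projected areas must be finite and non-negative")
  b <- cfg$area_class_bounds_cm2
  cut(A, breaks = c(-Inf, b, Inf), labels = AREA_CLASSES, right = FALSE)
}

#' Empirical pulp-yield table from manual depulping
#'
#' Measured pulp mass recovered from 100-g samples of roughly ten fruits,
#' for each commercial ripening stage and projected-area class. Shipped as
#' a plain CSV fixture and read at call time; the stage column of the
#' source table uses the label "Pinton Ripe", normalized here to
#' "Ripe Pinton".
#'
#' @return Tibble with columns `stage` (ordered factor), `pulp_g`,
#'   `sample_weight_g`, `area_class` (factor).
#' @export
#' @examples
#' pulp_yield_table()
pulp_yield_table <- function() {
  path <- system.file("extdata", "pulp_yield_table.csv",
                      package = "camuvision", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  tibble(
    stage = stage_factor(raw$stage),
    pulp_g = as.numeric(raw$pulp_g),
    sample_weight_g = as.numeric(raw$sample_weight_g),
    area_class = factor(raw$area_class, levels = AREA_CLASSES)
  )
}

#' Look up measured pulp yield by stage and area class
#'
#' Returns the depulping measurement for a commercial stage and area class.
#' Green fruit was not depulped (it is reserved for ripening), so Green is
#' rejected.
#'
#' @param stage Stage name(s); must be commercial.
#' @param cls Area class name(s), as in [area_class()] levels; recycled
#'   against `stage`.
#' @param table The yield table, by default [pulp_yield_table()].
#' @return Measured pulp mass(es) in grams.
#' @export
#' @examples
#' empirical_pulp_lookup("Ripe", "more_than_8")
empirical_pulp_lookup <- function(stage, cls, table = pulp_yield_table()) {
  s <- stage_factor(stage)
  if (any(s == "Green"))
    abort("no empirical pulp yield for the Green stage (non-commercial)")
  cls <- as.character(cls)
  if (!all(cls %in% AREA_CLASSES))
    abort(sprintf("unknown area class: %s",
                  paste(setdiff(cls, AREA_CLASSES), collapse = ", ")))
  n <- max(length(s), length(cls))
  s <- rep_len(as.character(s), n)
  cls <- rep_len(cls, n)
  key <- paste(s, cls)
  tab_key <- paste(as.character(table$stage), as.character(table$area_class))
  idx <- match(key, tab_key)
  if (anyNA(idx))
    abort(sprintf("no table entry for: %s", paste(key[is.na(idx)], collapse = "; ")))
  table$pulp_g[idx]
}

#' Refit the quadratic pulp calibration to the yield table
#'
#' Least-squares fit of the quadratic-in-area, linear-in-maturity form to
#' the nine depulping measurements, using a declared representative area
#' per area class (the source measurements only record the class, not the
#' area). This is a regression-stability utility: it documents how such a
#' calibration is obtained and lets users recalibrate from their own
#' depulping tables. It is not claimed to reproduce the shipped default
#' coefficients, whose underlying representative areas are unknown.
#'
#' @param table A yield table as returned by [pulp_yield_table()].
#' @param representative_areas Named numeric: area in cm^2 standing for each
#'   area class.
#' @param cfg A [calibration_config()] supplying the maturity mapping.
#' @return Named numeric coefficients `c(a2, a1, a0, aM)`.
#' @export
refit_pulp_calibration <- function(table = pulp_yield_table(),
                                   representative_areas = c(
                                     less_than_5 = 4.0,
                                     between_5_and_8 = 6.5,
                                     more_than_8 = 9.5
                                   ),
                                   cfg = calibration_config()) {
  stopifnot(all(AREA_CLASSES %in% names(representative_areas)))
  A <- unname(representative_areas[as.character(table$area_class)])
  M <- maturity_factor_of(table$stage, cfg)
  if (anyNA(M)) abort("yield table must contain commercial stages only")
  fit <- lm(pulp_g ~ I(A^2) + A + M, data = data.frame(pulp_g = table$pulp_g,
                                                       A = A, M = M))
  cf <- coef(fit)
  c(a2 = unname(cf[["I(A^2)"]]), a1 = unname(cf[["A"]]),
    a0 = unname(cf[["(Intercept)"]]), aM = unname(cf[["M"]]))
}
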