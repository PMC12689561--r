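#' Proportional ascorbic acid concentration estimate
#'
#' Scales a certified laboratory concentration by the ratio of the
#' system-estimated mass to the laboratory reference mass:
#' `R2 = R1 * b2 / b1`. With `b2 = b1` the laboratory value is returned
#' unchanged.
#'
#' @param R1 Certified laboratory concentration(s), mg per 100 g (> 0).
#' @param b2 System-estimated mass(es) in grams (>= 0).
#' @param b1 Laboratory reference mass(es) in grams (> 0).
#' @return Estimated concentration(s) R2 in mg per 100 g.
#' @export
#' @examples
#' estimate_concentration(2187.50, 12.30, 100)
estimate_concentration <- function(R1, b2, b1) {
  if (any(!is.finite(R1)) || any(R1 <= 0))
    abort("laboratory concentration R1 must be positive")
  if (any(!is.finite(b1)) || any(b1 <= 0))
    abort("reference mass b1 must be positive")
  if (any(!is.finite(b2)) || any(b2 < 0))
    abort("estimated mass b2 must be non-negative")
  R1 * b2 / b1
}

#' Total ascorbate content of one fruit
#'
#' Multiplies a concentration expressed per 100 g of pulp by the fruit's
#' pulp mass (the per-100-g concentration is divided by 100 first, so units
#' work out to mg of ascorbic acid).
#'
#' @param conc_mg_per_100g Concentration(s) in mg per 100 g (>= 0).
#' @param m_pulp Pulp mass(es) in grams (>= 0).
#' @return Total ascorbate in mg.
#' @export
#' @examples
#' fruit_total_ascorbate(2187.50, 10)  # 218.75 mg
fruit_total_ascorbate <- function(conc_mg_per_100g, m_pulp) {
  if (any(!is.finite(conc_mg_per_100g)) || any(conc_mg_per_100g < 0))
    abort("concentration must be non-negative")
  if (any(!is.finite(m_pulp)) || any(m_pulp < 0))
    abort("pulp mass must be non-negative")
  conc_mg_per_100g / 100 * m_pulp
}

#' Quantify staged detections into per-fruit records
#'
#' Takes staged detections and computes, per fruit: pixel and physical
#' area, maturity factor, pulp mass (quadratic area-maturity model by
#' default, or the thickness-density volumetric model), the proportional
#' concentration estimate R2, and the total ascorbate in mg (laboratory
#' concentration per gram times pulp mass). Green fruit — reserved for
#' ripening and excluded from commercial reporting — is flagged `excluded`
#' and carries no pulp/ascorbate values under the quadratic model (Green
#' has no maturity factor).
#'
#' @param detections Detection tibble (see [segment_fruits()] /
#'   [load_external_detections()]) with a `stage` column.
#' @param cfg A [calibration_config()].
#' @param pulp_model `"quadratic"` (default) or `"thickness"`.
#' @param shape_model Passed to [region_area_px()].
#' @return Tibble of fruit records with columns `stage`, `area_px`,
#'   `area_cm2`, `maturity`, `pulp_g`, `ascorbate_mg_per_100g`,
#'   `ascorbate_total_mg`, `excluded`.
#' @export
quantify_fruits <- function(detections, cfg = calibration_config(),
                            pulp_model = c("quadratic", "thickness"),
                            shape_model = c("auto", "mask", "ellipse")) {
  pulp_model <- match.arg(pulp_model)
  stopifnot(is.data.frame(detections))
  if (nrow(detections) == 0L) return(.empty_records())
  if (!"stage" %in% names(detections) || anyNA(detections$stage))
    abort("every detection must carry a ripeness stage")
  stage <- stage_factor(detections$stage)
  area_px <- region_area_px(detections, shape_model = match.arg(shape_model))
  area_cm2 <- px_area_to_cm2(area_px, cfg)
  maturity <- maturity_factor_of(stage, cfg)
  excluded <- stage == "Green"

  pulp_g <- rep(NA_real_, length(stage))
  keep <- !excluded
  if (pulp_model == "quadratic") {
    pulp_g[keep] <- pulp_from_area(area_cm2[keep], maturity[keep], cfg)
  } else {
    pulp_g[keep] <- pulp_mass_from_thickness(area_cm2[keep], cfg)
  }
  R1 <- unname(cfg$stage_reference_conc[as.character(stage)])
  conc <- rep(NA_real_, length(stage))
  total <- rep(NA_real_, length(stage))
  conc[keep] <- estimate_concentration(R1[keep], pulp_g[keep],
                                       cfg$reference_mass_g)
  total[keep] <- fruit_total_ascorbate(R1[keep], pulp_g[keep])

  tibble(
    stage = stage,
    area_px = area_px,
    area_cm2 = area_cm2,
    maturity = maturity,
    pulp_g = pulp_g,
    ascorbate_mg_per_100g = conc,
    ascorbate_total_mg = total,
    excluded = excluded
  )
}

.empty_records <- function() {
  tibble(
    stage = stage_factor(character(0)),
    area_px = numeric(0), area_cm2 = numeric(0), maturity = numeric(0),
    pulp_g = numeric(0), ascorbate_mg_per_100g = numeric(0),
    ascorbate_total_mg = numeric(0), excluded = logical(0)
  )
}

#' Aggregate fruit records into a per-image report
#'
#' Sums areas, pulp and total ascorbate over the non-excluded (commercial)
#' fruit of one image, and estimates a per-stage concentration by applying
#' the proportional estimator to each stage's total pulp mass against the
#' laboratory reference mass. An empty record list yields a report with
#' zero totals.
#'
#' @param records Fruit-record tibble from [quantify_fruits()].
#' @param cfg A [calibration_config()].
#' @return An object of class `camu_image_report`: a list with `records`,
#'   counts, totals, and a `per_stage` tibble (stage, n, pulp_g,
#'   reference and estimated concentration in mg/100 g).
#' @export
aggregate_image <- function(records, cfg = calibration_config()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) records <- .empty_records()
  stage <- stage_factor(records$stage)
  excluded <- if ("excluded" %in% names(records)) records$excluded else
    stage == "Green"
  keep <- records[!excluded, , drop = FALSE]

  per_stage <- keep |>
    dplyr::group_by(stage = stage_factor(.data$stage)) |>
    dplyr::summarise(
      n = dplyr::n(),
      pulp_g = sum(.data$pulp_g),
      total_ascorbate_mg = sum(.data$ascorbate_total_mg),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      reference_mg_per_100g =
        unname(cfg$stage_reference_conc[as.character(.data$stage)]),
      estimated_mg_per_100g = estimate_concentration(
        .data$reference_mg_per_100g, .data$pulp_g, cfg$reference_mass_g
      )
    )

  out <- list(
    records = records,
    n_fruits = nrow(records),
    n_excluded = sum(excluded),
    total_area_cm2 = sum(keep$area_cm2),
    total_pulp_g = sum(keep$pulp_g),
    total_ascorbate_mg = sum(keep$ascorbate_total_mg),
    per_stage = per_stage,
    schema_version = "1.0"
  )
  class(out) <- "camu_image_report"
  out
}

#' @export
print.camu_image_report <- function(x, ...) {
  cat("<camu_image_report>\n")
  cat(sprintf("  fruits: %d (%d Green excluded)\n", x$n_fruits, x$n_excluded))
  cat(sprintf("  total area: %.2f cm^2, total pulp: %.2f g, total ascorbate: %.1f mg\n",
              x$total_area_cm2, x$total_pulp_g, x$total_ascorbate_mg))
  if (nrow(x$per_stage)) {
    cat("  per-stage concentration estimate (mg/100 g):\n")
    for (i in seq_len(nrow(x$per_stage))) {
      cat(sprintf("    %-12s n=%2d  R2 = %.2f\n",
                  as.character(x$per_stage$stage[i]), x$per_stage$n[i],
                  x$per_stage$estimated_mg_per_100g[i]))
    }
  }
  invisible(x)
}

#' @rdname aggregate_image
#' @param x A `camu_image_report`.
#' @param ... Unused.
#' @return `tidy()` returns the per-fruit record tibble; `glance()` a
#'   one-row summary tibble.
#' @export
tidy.camu_image_report <- function(x, ...) x$records

#' @rdname aggregate_image
#' @export
glance.camu_image_report <- function(x, ...) {
  tibble(
    n_fruits = x$n_fruits,
    n_excluded = x$n_excluded,
    total_area_cm2 = x$total_area_cm2,
    total_pulp_g = x$total_pulp_g,
    total_ascorbate_mg = x$total_ascorbate_mg
  )
}

#' Serialize an image report
#'
#' Writes the nested report as JSON (full precision) and, optionally, the
#' per-fruit records as a flat CSV with one row per fruit.
#'
#' @param report A `camu_image_report`.
#' @param json_path Output JSON path, or `NULL` to skip.
#' @param csv_path Output CSV path, or `NULL` to skip.
#' @return The report, invisibly.
#' @export
write_image_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "camu_image_report"))
  if (!is.null(json_path)) {
    payload <- list(
      schema_version = report$schema_version,
      n_fruits = report$n_fruits,
      n_excluded = report$n_excluded,
      total_area_cm2 = report$total_area_cm2,
      total_pulp_g = report$total_pulp_g,
      total_ascorbate_mg = report$total_ascorbate_mg,
      per_stage = as.data.frame(report$per_stage),
      records = as.data.frame(dplyr::mutate(
        report$records, stage = as.character(.data$stage)
      ))
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csv_path)) {
    write.csv(dplyr::mutate(report$records,
                            stage = as.character(.data$stage)),
              csv_path, row.names = FALSE)
  }
  invisible(report)
}
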