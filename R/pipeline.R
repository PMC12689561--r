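#' Analyze images end to end
#'
#' Runs the full pipeline on a batch of images: read, detect and stage
#' fruit (reference color detector, or externally supplied COCO
#' detections), quantify each fruit, and aggregate a per-image report.
#' Unreadable inputs are recorded per file and do not stop the batch.
#'
#' @param images Character vector of image paths, or a list of in-memory
#'   H x W x 3 arrays.
#' @param cfg A [calibration_config()]; its `px_per_cm` must match the
#'   images' capture geometry.
#' @param detector `"reference"` (color segmentation) or `"coco"`
#'   (detections from `coco_path`, matched to images by `image_id` in file
#'   order).
#' @param coco_path COCO JSON path when `detector = "coco"`.
#' @param pulp_model `"quadratic"` or `"thickness"`; see
#'   [quantify_fruits()].
#' @param palette A [stage_palette()] for the reference detector.
#' @param min_area_px Minimum detection area; see [segment_fruits()].
#' @return A `camu_batch`: list with `reports` (one `camu_image_report`
#'   per readable image), `summary` (tibble, one row per image), and
#'   `errors` (tibble of failed inputs).
#' @export
analyze_images <- function(images, cfg = calibration_config(),
                           detector = c("reference", "coco"),
                           coco_path = NULL,
                           pulp_model = c("quadratic", "thickness"),
                           palette = default_stage_palette(),
                           min_area_px = NULL) {
  detector <- match.arg(detector)
  pulp_model <- match.arg(pulp_model)
  if (detector == "coco") {
    if (is.null(coco_path)) abort("detector = \"coco\" needs coco_path")
    ext <- load_external_detections(coco_path)
  }
  ids <- if (is.character(images)) images else
    paste0("image_", seq_along(images))

  reports <- list()
  errors <- tibble(image = character(0), error = character(0))
  for (i in seq_along(images)) {
    res <- tryCatch({
      dets <- if (detector == "reference") {
        segment_fruits(if (is.character(images)) images[[i]] else images[[i]],
                       palette = palette, min_area_px = min_area_px,
                       cfg = cfg)
      } else {
        dplyr::filter(ext, .data$image_id == i)
      }
      aggregate_image(quantify_fruits(dets, cfg, pulp_model = pulp_model),
                      cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- dplyr::bind_rows(errors,
                                 tibble(image = ids[[i]],
                                        error = conditionMessage(res)))
    } else {
      reports[[ids[[i]]]] <- res
    }
  }
  summary <- purrr::map_dfr(names(reports), function(nm) {
    dplyr::bind_cols(tibble(image = nm), glance(reports[[nm]]))
  })
  out <- list(reports = reports, summary = summary, errors = errors)
  class(out) <- "camu_batch"
  out
}

#' @export
print.camu_batch <- function(x, ...) {
  cat(sprintf("<camu_batch> %d image(s) analyzed, %d failed\n",
              length(x$reports), nrow(x$errors)))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Simulate a batch of synthetic scenes to disk
#'
#' Generates one PNG, one COCO ground-truth JSON and one per-fruit CSV per
#' scene, plus a manifest listing every artifact with its seed and MD5
#' checksum. Scene seeds default to `base_seed + 0:(n_scenes-1)` so a
#' batch is fully reproducible from one integer.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_scenes Number of scenes.
#' @param spec Template [scene_spec()]; each scene reuses it with its own
#'   seed.
#' @param base_seed First seed.
#' @return Tibble manifest (also written to `manifest.json` in `out_dir`).
#' @export
simulate_scenes <- function(out_dir, n_scenes = 1,
                            spec = scene_spec(), base_seed = spec$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map_dfr(seq_len(n_scenes), function(i) {
    seed_i <- as.integer(base_seed + i - 1L)
    sp <- spec; sp$seed <- seed_i
    sc <- generate_scene(sp)
    stem <- sprintf("scene_%03d", i)
    png_path <- file.path(out_dir, paste0(stem, ".png"))
    json_path <- file.path(out_dir, paste0(stem, ".json"))
    csv_path <- file.path(out_dir, paste0(stem, ".csv"))
    write_scene_png(sc, png_path)
    write_ground_truth(sc$ground_truth, json_path, sp$image_size_px,
                       csv_path = csv_path,
                       file_name = basename(png_path))
    tibble(
      scene = stem, seed = seed_i,
      image = basename(png_path), coco = basename(json_path),
      csv = basename(csv_path),
      image_md5 = unname(tools::md5sum(png_path)),
      coco_md5 = unname(tools::md5sum(json_path))
    )
  })
  jsonlite::write_json(as.data.frame(rows),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  rows
}

#' Evaluate paired concentrations from a file or table
#'
#' Thin wrapper over [stagewise_mape()] accepting a CSV path (columns
#' `stage`, `system_mg_per_100g`, `laboratory_mg_per_100g`) or a data
#' frame, optionally writing the result as JSON.
#'
#' @param pairs CSV path or tibble of paired values; defaults to the
#'   shipped certified comparison table.
#' @param out_json Optional output path for the JSON report.
#' @param include_green Passed to [stagewise_mape()].
#' @return A `camu_mape_report`.
#' @export
evaluate_mape <- function(pairs = reference_comparison_table(),
                          out_json = NULL, include_green = FALSE) {
  if (is.character(pairs)) {
    raw <- read.csv(pairs, stringsAsFactors = FALSE)
    pairs <- raw
  }
  rep <- stagewise_mape(as_tibble(pairs), include_green = include_green)
  if (!is.null(out_json)) {
    payload <- list(
      per_stage = as.data.frame(dplyr::mutate(
        rep$per_stage, stage = as.character(.data$stage))),
      mean_mape_pct = rep$mean_mape_pct
    )
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  rep
}
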