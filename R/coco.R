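COCO_CATEGORIES <- function() {
  tibble(id = 1:4, name = stage_levels())
}

#' Write detections as COCO-style JSON
#'
#' Serializes a detection table to the standard COCO object-detection
#' schema: an `images` entry, the four stage `categories`, and one
#' annotation per detection with a `[x, y, w, h]` bounding box (top-left
#' pixel origin, half-open) and a `score`.
#'
#' @param detections Detection tibble with `x`, `y`, `w`, `h`, `stage`,
#'   and optionally `confidence` and `area_px`.
#' @param path Output JSON path.
#' @param image_size_px Image side length(s) in px: one number (square) or
#'   `c(width, height)`.
#' @param file_name Image file name to record.
#' @param image_id Numeric image id (default 1).
#' @return `path`, invisibly.
#' @export
write_coco <- function(detections, path, image_size_px,
                       file_name = "image.png", image_id = 1L) {
  stopifnot(is.data.frame(detections))
  if (anyNA(stage_factor(detections$stage)) && nrow(detections) > 0)
    abort("every detection must carry a stage to be written as COCO")
  wh <- rep_len(image_size_px, 2L)
  cats <- COCO_CATEGORIES()
  anns <- purrr::map(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    area <- if ("area_px" %in% names(d)) d$area_px else d$w * d$h
    list(
      id = i, image_id = image_id,
      category_id = cats$id[match(as.character(stage_factor(d$stage)),
                                  cats$name)],
      bbox = c(d$x, d$y, d$w, d$h),
      area = area,
      score = if ("confidence" %in% names(d)) d$confidence else 1,
      iscrowd = 0L
    )
  })
  payload <- list(
    images = list(list(id = image_id, width = wh[1], height = wh[2],
                       file_name = file_name)),
    annotations = anns,
    categories = purrr::map(seq_len(nrow(cats)), function(i) {
      list(id = cats$id[i], name = cats$name[i], supercategory = "fruit")
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load external detections from COCO-style JSON
#'
#' Adapter for detections produced outside the package (e.g. by a trained
#' object detector): reads a COCO-style annotation file whose category
#' names match the four ripeness stages and returns them as the package's
#' detection tibble. Unknown categories and malformed records are rejected
#' with an error naming the offending annotation.
#'
#' @param path Path to a COCO-style JSON file.
#' @return Detection tibble with `x`, `y`, `w`, `h`, `area_px`,
#'   `confidence`, `stage`, `image_id`.
#' @export
load_external_detections <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) abort(sprintf(
                    "malformed COCO JSON '%s': %s", path, conditionMessage(e))))
  if (is.null(doc$categories)) abort("COCO file has no 'categories' block")
  cat_names <- vapply(doc$categories, function(c) as.character(c$name),
                      character(1))
  cat_ids <- vapply(doc$categories, function(c) as.numeric(c$id), numeric(1))
  known <- vapply(cat_names, function(nm) {
    !inherits(try(stage_factor(nm), silent = TRUE), "try-error")
  }, logical(1))

  anns <- doc$annotations
  if (is.null(anns) || length(anns) == 0L) {
    out <- .empty_detections()
    out$image_id <- numeric(0)
    out$mask <- NULL
    return(out)
  }
  purrr::map_dfr(seq_along(anns), function(i) {
    a <- anns[[i]]
    if (is.null(a$bbox) || length(a$bbox) != 4L)
      abort(sprintf("annotation %d: missing or malformed bbox", i))
    ci <- match(as.numeric(a$category_id), cat_ids)
    if (is.na(ci))
      abort(sprintf("annotation %d: unknown category_id %s", i,
                    as.character(a$category_id)))
    if (!known[ci])
      abort(sprintf("annotation %d: category '%s' is not a ripeness stage",
                    i, cat_names[ci]))
    bb <- as.numeric(a$bbox)
    if (any(!is.finite(bb)) || bb[3] <= 0 || bb[4] <= 0)
      abort(sprintf("annotation %d: degenerate bbox", i))
    tibble(
      x = bb[1], y = bb[2], w = bb[3], h = bb[4],
      area_px = if (!is.null(a$area)) as.numeric(a$area) else bb[3] * bb[4],
      confidence = if (!is.null(a$score)) as.numeric(a$score) else 1,
      stage = stage_factor(cat_names[ci]),
      image_id = if (!is.null(a$image_id)) as.numeric(a$image_id) else 1
    )
  })
}
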