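#' Stage color palette
#'
#' Prototype colors for the four ripeness stages, used by the reference
#' detector to stage fruit by nearest prototype. The four stages are
#' defined visually (green, yellow-green turning, orange-red turning, dark
#' red), not by any published color thresholds, so the prototypes are a
#' configurable fixture rather than a measured standard. Classification
#' distances are computed in a hue/saturation/value feature space for
#' illumination robustness.
#'
#' @param colors 4x3 numeric matrix of sRGB prototypes in `[0, 1]`, rows
#'   named by stage.
#' @return A `camu_palette`: tibble with columns `stage`, `r`, `g`, `b`.
#' @export
#' @examples
#' default_stage_palette()
stage_palette <- function(colors) {
  stopifnot(is.matrix(colors), ncol(colors) == 3, nrow(colors) == 4)
  stage <- stage_factor(rownames(colors))
  if (anyDuplicated(stage)) abort("palette must name each stage once")
  if (any(colors < 0) || any(colors > 1))
    abort("palette colors must lie in [0, 1]")
  if (anyDuplicated(round(colors, 6)))
    abort("palette prototypes must be pairwise distinct")
  out <- tibble(stage = stage, r = colors[, 1], g = colors[, 2],
                b = colors[, 3])
  out <- dplyr::arrange(out, .data$stage)
  class(out) <- c("camu_palette", class(out))
  out
}

#' @rdname stage_palette
#' @export
default_stage_palette <- function() {
  stage_palette(matrix(
    c(0.30, 0.55, 0.20,   # Green: leaf green
      0.68, 0.60, 0.18,   # Pinton Green: yellow-green turning
      0.75, 0.28, 0.18,   # Ripe Pinton: orange-red turning
      0.42, 0.08, 0.14),  # Ripe: dark purplish red
    ncol = 3, byrow = TRUE,
    dimnames = list(stage_levels(), c("r", "g", "b"))
  ))
}

# Map sRGB (3 x n, in [0,1]) to a hue/saturation/value feature space where
# Euclidean distance respects hue circularity: (s*cos(2*pi*h), s*sin(2*pi*h), v).
.hsv_feature <- function(rgb) {
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  rbind(hsv[2, ] * cospi(2 * hsv[1, ]),
        hsv[2, ] * sinpi(2 * hsv[1, ]),
        hsv[3, ])
}

# Per-pixel saturation of an H x W x 3 array.
.saturation <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

#' Detect fruit regions by color segmentation
#'
#' Reference detector for scenes of fruit on a near-neutral background:
#' foreground pixels are those whose saturation exceeds a threshold,
#' connected components above a minimum area become detections, each with
#' a tight bounding box (top-left origin, zero-based, half-open `(x, y, w,
#' h)`) and a cropped binary mask. Confidence is 1 for every detection
#' (the detector is deterministic). Touching fruits are not split; the
#' synthetic generator guarantees non-overlap by default.
#'
#' @param image H x W x 3 numeric array in `[0, 1]`, or a path to a PNG/JPEG
#'   file.
#' @param palette A [stage_palette()] used when `classify = TRUE`.
#' @param min_area_px Minimum component area in px; defaults to the pixel
#'   equivalent of 0.1 cm^2 at the configured scale.
#' @param cfg A [calibration_config()] (supplies the scale for the default
#'   `min_area_px`).
#' @param sat_threshold Background saturation threshold (default 0.15).
#' @param classify If `TRUE` (default), stage each detection with
#'   [classify_stage()].
#' @return Detection tibble: `x`, `y`, `w`, `h`, `area_px`, `confidence`,
#'   `stage` (ordered factor, `NA` if `classify = FALSE`), `mask`
#'   (list-column of logical matrices aligned to each box).
#' @export
segment_fruits <- function(image, palette = default_stage_palette(),
                           min_area_px = NULL, cfg = calibration_config(),
                           sat_threshold = 0.15, classify = TRUE) {
  img <- read_image(image)
  if (is.null(min_area_px)) min_area_px <- 0.1 * cfg$px_per_cm^2

  fg <- .saturation(img) > sat_threshold
  labels <- EBImage::bwlabel(fg)
  n_lab <- max(labels)
  if (n_lab == 0L) return(.empty_detections())

  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  areas <- tabulate(lab, nbins = n_lab)
  row_min <- tapply(idx[, 1], lab, min)
  row_max <- tapply(idx[, 1], lab, max)
  col_min <- tapply(idx[, 2], lab, min)
  col_max <- tapply(idx[, 2], lab, max)

  keep <- which(areas >= min_area_px)
  if (!length(keep)) return(.empty_detections())

  dets <- purrr::map_dfr(keep, function(k) {
    kk <- as.character(k)
    r0 <- row_min[[kk]]; r1 <- row_max[[kk]]
    c0 <- col_min[[kk]]; c1 <- col_max[[kk]]
    tibble(
      x = c0 - 1, y = r0 - 1, w = c1 - c0 + 1, h = r1 - r0 + 1,
      area_px = areas[k], confidence = 1,
      mask = list(labels[r0:r1, c0:c1, drop = FALSE] == k)
    )
  })
  dets$stage <- if (classify) classify_stage(img, dets, palette) else
    stage_factor(rep(NA_character_, nrow(dets)))[seq_len(nrow(dets))]
  dets[, c("x", "y", "w", "h", "area_px", "confidence", "stage", "mask")]
}

.empty_detections <- function() {
  tibble(
    x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
    area_px = numeric(0), confidence = numeric(0),
    stage = stage_factor(character(0)), mask = list()
  )
}

#' Stage detections by nearest color prototype
#'
#' Computes the mean color of each detection (over its mask when present,
#' otherwise over its whole box), maps it to the hue/saturation/value
#' feature space, and assigns the nearest palette prototype by Euclidean
#' distance. Exact ties break toward the lower ripeness ordinal.
#'
#' @param image H x W x 3 numeric array in `[0, 1]`.
#' @param detections Detection tibble with `x`, `y`, `w`, `h` and optional
#'   `mask`.
#' @param palette A [stage_palette()].
#' @return Ordered factor of stages, one per detection.
#' @export
classify_stage <- function(image, detections,
                           palette = default_stage_palette()) {
  img <- read_image(image)
  stopifnot(is.data.frame(detections))
  if (nrow(detections) == 0L) return(stage_factor(character(0)))
  proto <- .hsv_feature(t(as.matrix(palette[, c("r", "g", "b")])))
  has_mask <- if ("mask" %in% names(detections)) {
    vapply(detections$mask, Negate(is.null), logical(1))
  } else rep(FALSE, nrow(detections))

  pick <- vapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    rows <- (d$y + 1):(d$y + d$h)
    cols <- (d$x + 1):(d$x + d$w)
    sub <- img[rows, cols, 1:3, drop = FALSE]
    sel <- if (has_mask[i]) detections$mask[[i]] else
      matrix(TRUE, d$h, d$w)
    if (!any(sel)) abort("cannot stage an empty detection region")
    mean_rgb <- vapply(1:3, function(ch) mean(sub[, , ch][sel]), numeric(1))
    f <- .hsv_feature(matrix(mean_rgb, ncol = 1))
    d2 <- colSums((proto - as.vector(f))^2)
    # which.min returns the first (lowest-ordinal) stage on exact ties
    which.min(round(d2, 12))
  }, integer(1))
  stage_factor(as.character(palette$stage[pick]))
}

#' Read an RGB image
#'
#' Accepts an in-memory H x W x 3 array (returned unchanged), a PNG path
#' (read with the png package), or another raster format readable by
#' EBImage (e.g. JPEG). Alpha channels are dropped; grayscale input is
#' rejected.
#'
#' @param x Array or file path.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
read_image <- function(x) {
  if (is.array(x)) {
    if (length(dim(x)) != 3L || dim(x)[3] < 3L)
      abort("image must be a 3-channel RGB raster")
    if (dim(x)[3] == 3L) return(x)
    return(x[, , 1:3, drop = FALSE])
  }
  if (!is.character(x) || length(x) != 1L)
    abort("image must be an RGB array or a single file path")
  if (!file.exists(x)) abort(sprintf("image file not found: %s", x))
  if (tolower(tools::file_ext(x)) == "png") {
    img <- png::readPNG(x)
  } else {
    eb <- EBImage::readImage(x)
    img <- aperm(EBImage::imageData(eb), c(2, 1, 3))  # EBImage is x-major
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    abort(sprintf("not a 3-channel RGB image: %s", x))
  img[, , 1:3, drop = FALSE]
}
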