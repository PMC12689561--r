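#' Specification of a synthetic camu-camu scene
#'
#' Describes one synthetic image emulating the acquisition geometry of the
#' study setup: roughly fifteen near-spherical fruits at mixed ripeness
#' stages on a neutral background, photographed from directly above at a
#' fixed distance. The default canvas is 1024 px square — a scaled
#' stand-in for the 3024 px frames — and the pixel scale shrinks by the
#' same factor (143.79 px/cm x 1024/3024 by default) so physical areas are
#' preserved.
#'
#' @param image_size_px Square canvas side in px (default 1024).
#' @param px_per_cm Linear scale; defaults to `143.79 * image_size_px / 3024`.
#' @param n_fruits Number of fruits to place (default 15).
#' @param stage_mix Probability vector over the four stages, in ripeness
#'   order; must sum to 1. Default weights Ripe at 0.4 and the others at
#'   0.2, mirroring the stage balance of typical harvest trays.
#' @param fruit_diameter_range_cm Range of fruit diameters in cm (default
#'   2.0–3.2; camu-camu berries run 2–3 cm).
#' @param aspect_range Range of minor/major semi-axis ratios (default
#'   0.85–1; the berries are near-spherical).
#' @param overlap_allowed If `FALSE` (default) fruit placements are
#'   rejection-sampled until bounding circles are disjoint.
#' @param gaussian_sigma Additive Gaussian pixel noise sd (default 0, i.e.
#'   noiseless).
#' @param highlight_prob Per-fruit probability of a specular highlight
#'   (default 0).
#' @param blur_sigma Gaussian blur sd in px applied to the final image
#'   (default 0).
#' @param background Neutral background color, sRGB triple.
#' @param seed Integer seed; every stochastic draw (placement, sizes,
#'   stages, noise) derives from it, so scenes are byte-reproducible.
#' @return A `camu_scene_spec` list.
#' @export
#' @examples
#' sp <- scene_spec(n_fruits = 5, image_size_px = 320, seed = 7)
#' sc <- generate_scene(sp)
#' sc$ground_truth
scene_spec <- function(image_size_px = 1024,
                       px_per_cm = 143.79 * image_size_px / 3024,
                       n_fruits = 15,
                       stage_mix = c(0.2, 0.2, 0.2, 0.4),
                       fruit_diameter_range_cm = c(2.0, 3.2),
                       aspect_range = c(0.85, 1),
                       overlap_allowed = FALSE,
                       gaussian_sigma = 0,
                       highlight_prob = 0,
                       blur_sigma = 0,
                       background = c(0.82, 0.82, 0.80),
                       seed = 1L) {
  stopifnot(image_size_px >= 64, px_per_cm > 0, n_fruits >= 0)
  if (length(stage_mix) != 4L || any(stage_mix < 0) ||
      abs(sum(stage_mix) - 1) > 1e-8)
    abort("stage_mix must be four non-negative probabilities summing to 1")
  if (length(fruit_diameter_range_cm) != 2L ||
      any(fruit_diameter_range_cm <= 0) || diff(fruit_diameter_range_cm) < 0)
    abort("fruit_diameter_range_cm must be a positive non-decreasing pair")
  if (any(aspect_range <= 0) || any(aspect_range > 1))
    abort("aspect_range must lie in (0, 1]")
  if (gaussian_sigma < 0 || blur_sigma < 0 ||
      highlight_prob < 0 || highlight_prob > 1)
    abort("noise parameters out of range")
  spec <- list(
    image_size_px = as.integer(image_size_px), px_per_cm = px_per_cm,
    n_fruits = as.integer(n_fruits), stage_mix = stage_mix,
    fruit_diameter_range_cm = fruit_diameter_range_cm,
    aspect_range = aspect_range, overlap_allowed = isTRUE(overlap_allowed),
    gaussian_sigma = gaussian_sigma, highlight_prob = highlight_prob,
    blur_sigma = blur_sigma, background = background,
    seed = as.integer(seed)
  )
  class(spec) <- "camu_scene_spec"
  spec
}

#' Generate a synthetic scene with exact ground truth
#'
#' Renders stage-colored rotated ellipses on a neutral background and
#' returns the raster together with the generative ground truth: per fruit,
#' the ellipse parameters, stage, analytic areas (`pi*a*b` in px^2 and its
#' cm^2 conversion), the bounding box, and the downstream expectations
#' (pulp mass via the quadratic model, per-fruit concentration R2 and
#' total ascorbate) computed from the analytic area. Green fruit carries
#' `NA` expectations, matching its exclusion from reporting. Placement is
#' rejection-sampled to keep fruits disjoint unless `overlap_allowed`;
#' failure to place all fruits raises a capacity error.
#'
#' @param spec A [scene_spec()].
#' @param palette A [stage_palette()] giving the fill color per stage.
#' @return A `camu_scene` list: `image` (H x W x 3 array), `ground_truth`
#'   (tibble), `spec`, and `cfg` (a [calibration_config()] at the scene's
#'   scale).
#' @export
generate_scene <- function(spec, palette = default_stage_palette()) {
  stopifnot(inherits(spec, "camu_scene_spec"))
  cfg <- calibration_config(px_per_cm = spec$px_per_cm)
  withr::with_seed(spec$seed, .render_scene(spec, palette, cfg))
}

.render_scene <- function(spec, palette, cfg) {
  n <- spec$n_fruits
  size <- spec$image_size_px
  # per-channel matrices so painting mutates in place (no full-array copies)
  chan <- lapply(spec$background, function(v) matrix(v, size, size))

  gt <- .place_fruits(spec)
  pal <- palette[match(as.character(gt$stage), as.character(palette$stage)), ]

  if (n > 0) {
    for (i in seq_len(nrow(gt))) {
      idx <- .ellipse_px(size, size, gt$cx[i], gt$cy[i], gt$a_px[i],
                         gt$b_px[i], gt$theta[i])
      col <- c(pal$r[i], pal$g[i], pal$b[i])
      for (ch in 1:3) chan[[ch]][idx] <- col[ch]
      if (spec$highlight_prob > 0 && runif(1) < spec$highlight_prob) {
        hx <- gt$cx[i] - 0.35 * gt$a_px[i] * cos(gt$theta[i])
        hy <- gt$cy[i] - 0.35 * gt$b_px[i] * sin(gt$theta[i])
        hidx <- .ellipse_px(size, size, hx, hy, 0.15 * gt$a_px[i],
                            0.12 * gt$b_px[i], gt$theta[i])
        hcol <- c(0.97, 0.97, 0.95)
        for (ch in 1:3) chan[[ch]][hidx] <- hcol[ch]
      }
    }
  }
  img <- array(c(chan[[1]], chan[[2]], chan[[3]]), dim = c(size, size, 3))
  if (spec$blur_sigma > 0) {
    for (ch in 1:3) {
      img[, , ch] <- EBImage::gblur(img[, , ch], sigma = spec$blur_sigma)
    }
  }
  if (spec$gaussian_sigma > 0) {
    img <- img + array(rnorm(length(img), 0, spec$gaussian_sigma), dim(img))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  gt <- .add_expectations(gt, cfg)
  out <- list(image = img, ground_truth = gt, spec = spec, cfg = cfg)
  class(out) <- "camu_scene"
  out
}

# Rejection-sample non-overlapping ellipse placements.
.place_fruits <- function(spec) {
  n <- spec$n_fruits
  size <- spec$image_size_px
  if (n == 0L) {
    return(tibble(
      fruit_id = integer(0), cx = numeric(0), cy = numeric(0),
      a_px = numeric(0), b_px = numeric(0), theta = numeric(0),
      stage = stage_factor(character(0))
    ))
  }
  stages <- sample(stage_levels(), n, replace = TRUE, prob = spec$stage_mix)
  d_cm <- runif(n, spec$fruit_diameter_range_cm[1],
                spec$fruit_diameter_range_cm[2])
  a <- d_cm / 2 * spec$px_per_cm
  b <- a * runif(n, spec$aspect_range[1], spec$aspect_range[2])
  theta <- runif(n, 0, pi)

  cx <- numeric(n); cy <- numeric(n)
  max_attempts <- 500L * n
  attempts <- 0L
  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        abort(sprintf(
          "capacity error: could not place %d non-overlapping fruits on a %d px canvas",
          n, size))
      r <- a[i] + 2
      x <- runif(1, r, size - r)
      y <- runif(1, r, size - r)
      if (spec$overlap_allowed || i == 1L ||
          all(sqrt((cx[seq_len(i - 1)] - x)^2 +
                   (cy[seq_len(i - 1)] - y)^2) >
              a[seq_len(i - 1)] + a[i] + 2)) {
        cx[i] <- x; cy[i] <- y
        break
      }
    }
  }
  tibble(fruit_id = seq_len(n), cx = cx, cy = cy, a_px = a, b_px = b,
         theta = theta, stage = stage_factor(stages))
}

# Linear indices of the pixels inside the rotated ellipse (cx, cy, a, b,
# theta), testing pixel centers (col - 0.5, row - 0.5) in zero-based
# continuous coordinates on a size_r x size_c grid.
.ellipse_px <- function(size_r, size_c, cx, cy, a, b, theta) {
  half <- max(a, b) + 1
  r0 <- max(1L, floor(cy - half)); r1 <- min(size_r, ceiling(cy + half))
  c0 <- max(1L, floor(cx - half)); c1 <- min(size_c, ceiling(cx + half))
  if (r0 > r1 || c0 > c1) return(integer(0))
  xs <- (c0:c1) - 0.5 - cx
  ys <- (r0:r1) - 0.5 - cy
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  U <- cos(theta) * X + sin(theta) * Y
  V <- -sin(theta) * X + cos(theta) * Y
  inside <- which((U / a)^2 + (V / b)^2 <= 1, arr.ind = TRUE)
  (c0 - 1L + inside[, 2] - 1L) * size_r + (r0 - 1L + inside[, 1])
}

# Analytic areas, bounding boxes and downstream expectations.
.add_expectations <- function(gt, cfg) {
  if (nrow(gt) == 0L) {
    gt$x <- gt$y <- gt$w <- gt$h <- numeric(0)
    gt$area_px <- gt$area_cm2 <- gt$pulp_g <- numeric(0)
    gt$conc_mg_per_100g <- gt$total_mg <- numeric(0)
    return(gt)
  }
  # tight axis-aligned bounds of a rotated ellipse
  hw <- sqrt((gt$a_px * cos(gt$theta))^2 + (gt$b_px * sin(gt$theta))^2)
  hh <- sqrt((gt$a_px * sin(gt$theta))^2 + (gt$b_px * cos(gt$theta))^2)
  gt$x <- gt$cx - hw
  gt$y <- gt$cy - hh
  gt$w <- 2 * hw
  gt$h <- 2 * hh
  gt$area_px <- pi * gt$a_px * gt$b_px
  gt$area_cm2 <- px_area_to_cm2(gt$area_px, cfg)
  m <- maturity_factor_of(gt$stage, cfg)
  keep <- !is.na(m)
  gt$pulp_g <- NA_real_
  gt$pulp_g[keep] <- pulp_from_area(gt$area_cm2[keep], m[keep], cfg)
  R1 <- unname(cfg$stage_reference_conc[as.character(gt$stage)])
  gt$conc_mg_per_100g <- NA_real_
  gt$conc_mg_per_100g[keep] <- estimate_concentration(
    R1[keep], gt$pulp_g[keep], cfg$reference_mass_g)
  gt$total_mg <- NA_real_
  gt$total_mg[keep] <- fruit_total_ascorbate(R1[keep], gt$pulp_g[keep])
  gt
}

#' @export
print.camu_scene <- function(x, ...) {
  cat(sprintf("<camu_scene> %d x %d px, %.2f px/cm, %d fruits (seed %d)\n",
              x$spec$image_size_px, x$spec$image_size_px, x$spec$px_per_cm,
              nrow(x$ground_truth), x$spec$seed))
  invisible(x)
}

#' Write a scene's ground truth to COCO JSON and CSV
#'
#' The COCO file lists the four stage categories and one annotation per
#' fruit (tight axis-aligned bounding box of its ellipse); the optional CSV
#' carries the full per-fruit ground truth with the expected downstream
#' quantities.
#'
#' @param gt Ground-truth tibble from [generate_scene()].
#' @param json_path Output COCO JSON path.
#' @param image_size_px Canvas side in px (recorded in the COCO `images`
#'   entry).
#' @param csv_path Optional CSV output path.
#' @param file_name Image file name recorded in the COCO entry.
#' @return `json_path`, invisibly.
#' @export
write_ground_truth <- function(gt, json_path, image_size_px,
                               csv_path = NULL, file_name = "scene.png") {
  write_coco(
    tibble(x = gt$x, y = gt$y, w = gt$w, h = gt$h,
           confidence = rep(1, nrow(gt)), stage = gt$stage),
    json_path, image_size_px = image_size_px, file_name = file_name
  )
  if (!is.null(csv_path)) {
    out <- dplyr::mutate(gt, stage = as.character(.data$stage))
    write.csv(as.data.frame(out), csv_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' Write a scene image as PNG
#'
#' @param scene A `camu_scene` (or a bare H x W x 3 array).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_scene_png <- function(scene, path) {
  img <- if (inherits(scene, "camu_scene")) scene$image else scene
  png::writePNG(img, path)
  invisible(path)
}
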