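#' Mean absolute percentage error
#'
#' `MAPE = 100/n * sum(|y - yhat| / y)` over paired laboratory (`y`) and
#' system (`yhat`) values. Laboratory values must be strictly positive
#' (the definition divides by them).
#'
#' @param y Laboratory (reference) values, all > 0.
#' @param yhat System (predicted) values, same length.
#' @return MAPE in percent.
#' @export
#' @examples
#' mape(c(100, 100), c(110, 90))  # 10
mape <- function(y, yhat) {
  if (length(y) == 0L) abort("MAPE needs at least one pair")
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  if (any(!is.finite(y)) || any(y <= 0))
    abort("laboratory values must be positive (MAPE divides by them)")
  if (any(!is.finite(yhat))) abort("predicted values must be finite")
  mean(abs((y - yhat) / y)) * 100
}

#' Certified laboratory vs. system concentration pairs
#'
#' The validation table of certified laboratory concentrations and the
#' system's estimates (mg/100 g) for the three commercial stages, shipped
#' as a CSV fixture. These printed pairs are the input of the headline
#' error analysis.
#'
#' @return Tibble with columns `stage`, `system_mg_per_100g`,
#'   `laboratory_mg_per_100g`.
#' @export
reference_comparison_table <- function() {
  path <- system.file("extdata", "stage_concentration_comparison.csv",
                      package = "camuvision", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  tibble(
    stage = stage_factor(raw$stage),
    system_mg_per_100g = as.numeric(raw$system_mg_per_100g),
    laboratory_mg_per_100g = as.numeric(raw$laboratory_mg_per_100g)
  )
}

#' Per-stage MAPE report
#'
#' Computes the MAPE per ripeness stage from paired laboratory/system
#' values and their unweighted arithmetic mean across stages. Green fruit
#' is not commercialized, so it is excluded from the error analysis by
#' default; passing data containing Green without `include_green = TRUE`
#' drops those rows with a warning.
#'
#' @param pairs Tibble with columns `stage`, `laboratory_mg_per_100g`,
#'   `system_mg_per_100g` (one or more pairs per stage).
#' @param include_green Include Green-stage pairs (default `FALSE`).
#' @return A `camu_mape_report`: list with `per_stage` (tibble of stage,
#'   n, mape_pct) and `mean_mape_pct`.
#' @export
#' @examples
#' stagewise_mape(reference_comparison_table())
stagewise_mape <- function(pairs, include_green = FALSE) {
  stopifnot(is.data.frame(pairs))
  need <- c("stage", "laboratory_mg_per_100g", "system_mg_per_100g")
  if (!all(need %in% names(pairs)))
    abort(sprintf("pairs must have columns: %s", paste(need, collapse = ", ")))
  pairs <- dplyr::mutate(pairs, stage = stage_factor(.data$stage))
  if (!include_green && any(pairs$stage == "Green")) {
    warn("Green-stage pairs excluded from the error analysis (non-commercial); set include_green = TRUE to keep them")
    pairs <- dplyr::filter(pairs, .data$stage != "Green")
  }
  if (nrow(pairs) == 0L) abort("no pairs left to evaluate")
  per_stage <- pairs |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n = dplyr::n(),
      mape_pct = mape(.data$laboratory_mg_per_100g,
                      .data$system_mg_per_100g),
      .groups = "drop"
    )
  out <- list(per_stage = per_stage,
              mean_mape_pct = mean(per_stage$mape_pct))
  class(out) <- "camu_mape_report"
  out
}

#' @export
print.camu_mape_report <- function(x, ...) {
  cat("<camu_mape_report>\n")
  for (i in seq_len(nrow(x$per_stage))) {
    cat(sprintf("  %-12s MAPE = %5.2f%%  (n = %d)\n",
                as.character(x$per_stage$stage[i]),
                x$per_stage$mape_pct[i], x$per_stage$n[i]))
  }
  cat(sprintf("  mean MAPE  = %5.2f%%\n", x$mean_mape_pct))
  invisible(x)
}

#' @rdname stagewise_mape
#' @param x A `camu_mape_report`.
#' @param ... Unused.
#' @export
tidy.camu_mape_report <- function(x, ...) x$per_stage

#' @rdname stagewise_mape
#' @export
glance.camu_mape_report <- function(x, ...) {
  tibble(n_stages = nrow(x$per_stage), mean_mape_pct = x$mean_mape_pct)
}

#' Intersection-over-union of axis-aligned boxes
#'
#' @param a,b Data frames of boxes with columns `x`, `y`, `w`, `h`
#'   (top-left origin, half-open).
#' @return `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
bbox_iou <- function(a, b) {
  .check_boxes(a); .check_boxes(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    ix <- pmax(0, pmin(a$x[i] + a$w[i], b$x + b$w) - pmax(a$x[i], b$x))
    iy <- pmax(0, pmin(a$y[i] + a$h[i], b$y + b$h) - pmax(a$y[i], b$y))
    inter <- ix * iy
    union <- a$w[i] * a$h[i] + b$w * b$h - inter
    out[i, ] <- inter / union
  }
  out
}

.check_boxes <- function(d) {
  stopifnot(is.data.frame(d))
  if (!all(c("x", "y", "w", "h") %in% names(d)))
    abort("boxes need columns x, y, w, h")
  if (nrow(d) > 0 &&
      (any(!is.finite(c(d$x, d$y, d$w, d$h))) || any(d$w <= 0) || any(d$h <= 0)))
    abort("malformed boxes: w and h must be positive and finite")
  invisible(d)
}

#' Detection precision, recall and F1 at a fixed IoU threshold
#'
#' Matches predictions to ground truth one-to-one at the given IoU
#' threshold, maximizing the number of matched pairs: predictions are
#' seeded in order of descending confidence, each preferring the
#' admissible ground-truth box of highest IoU, and the matching is then
#' augmented to maximum cardinality, so the true-positive count is the
#' optimal assignment (confidence and IoU only break ties among maximum
#' matchings). Precision is TP/(TP+FP), recall TP/(TP+FN), F1 their
#' harmonic mean. Conventions at the edges: with no predictions and
#' non-empty ground truth, precision is 0; with both lists empty all three
#' metrics are 1; predictions against empty ground truth score precision 0.
#'
#' @param gt Ground-truth boxes (`x`, `y`, `w`, `h`).
#' @param pred Predicted boxes (`x`, `y`, `w`, `h`, optional `confidence`).
#' @param iou_threshold Matching threshold in (0, 1), default 0.5.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
detection_pr <- function(gt, pred, iou_threshold = 0.5) {
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold >= 1)
    abort("iou_threshold must lie in (0, 1)")
  .check_boxes(gt); .check_boxes(pred)
  n_gt <- nrow(gt); n_pred <- nrow(pred)
  tp <- 0L
  if (n_gt > 0 && n_pred > 0) {
    conf <- if ("confidence" %in% names(pred)) pred$confidence else
      rep(1, n_pred)
    iou <- bbox_iou(pred, gt)
    ord <- order(-conf, -apply(iou, 1, max))
    # Kuhn's augmenting-path matching seeded in confidence order; each
    # prediction tries ground-truth boxes by descending IoU
    match_of_gt <- rep(0L, n_gt)
    for (i in ord) {
      visited <- rep(FALSE, n_gt)
      augment <- function(p) {
        for (j in order(-iou[p, ])) {
          if (iou[p, j] < iou_threshold) break
          if (visited[j]) next
          visited[j] <<- TRUE
          if (match_of_gt[j] == 0L || augment(match_of_gt[j])) {
            match_of_gt[j] <<- p
            return(TRUE)
          }
        }
        FALSE
      }
      if (augment(i)) tp <- tp + 1L
    }
  }
  fp <- n_pred - tp
  fn <- n_gt - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (n_gt == 0) 1 else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (n_pred == 0) 1 else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}

#' Stage confusion matrix and macro metrics
#'
#' Cross-tabulates aligned ground-truth and predicted stage labels over
#' the four ripeness stages (rows = truth, columns = prediction) and
#' derives accuracy plus macro-averaged precision, recall and F1.
#' Classes absent from both truth and prediction contribute no defined
#' per-class metric and are dropped from the macro averages.
#'
#' @param gt_stages,pred_stages Equal-length vectors of stage labels.
#' @return A `camu_confusion`: list with `matrix` (4x4 counts),
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`, and
#'   `per_class` tibble.
#' @export
stage_confusion <- function(gt_stages, pred_stages) {
  g <- stage_factor(gt_stages)
  p <- stage_factor(pred_stages)
  if (length(g) != length(p))
    abort("ground-truth and predicted label lists must have equal length")
  if (length(g) == 0L) abort("no labels to compare")
  m <- table(truth = g, prediction = p)
  m <- unclass(m)
  diagm <- diag(m)
  row_s <- rowSums(m); col_s <- colSums(m)
  prec <- ifelse(col_s > 0, diagm / col_s, NA_real_)
  rec <- ifelse(row_s > 0, diagm / row_s, NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec),
               ifelse(is.na(prec) | is.na(rec), NA_real_, 0))
  present <- row_s > 0 | col_s > 0
  per_class <- tibble(
    stage = stage_factor(rownames(m)),
    n_truth = as.integer(row_s),
    precision = as.numeric(prec),
    recall = as.numeric(rec),
    f1 = as.numeric(f1)
  )
  out <- list(
    matrix = m,
    accuracy = sum(diagm) / length(g),
    macro_precision = mean(prec[present], na.rm = TRUE),
    macro_recall = mean(rec[present], na.rm = TRUE),
    macro_f1 = mean(f1[present], na.rm = TRUE),
    per_class = per_class
  )
  class(out) <- "camu_confusion"
  out
}

#' @export
print.camu_confusion <- function(x, ...) {
  cat("<camu_confusion>\n")
  print(x$matrix)
  cat(sprintf("accuracy %.3f | macro P %.3f R %.3f F1 %.3f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' @rdname stage_confusion
#' @param x A `camu_confusion`.
#' @param ... Unused.
#' @export
tidy.camu_confusion <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$matrix), stringsAsFactors = FALSE)) |>
    setNames(c("truth", "prediction", "n"))
}

#' @rdname stage_confusion
#' @export
glance.camu_confusion <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
         macro_recall = x$macro_recall, macro_f1 = x$macro_f1)
}
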