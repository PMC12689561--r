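# Independent oracles used across test files. These are deliberately
# brute-force / closed-form and never call the code paths they check.

# Round half away from zero to `digits` decimals (printed-table convention).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Horner-free polynomial evaluation for the pulp model, written as an
# explicit sum of terms (independent of pulp_from_area()).
oracle_pulp <- function(A, M, a2 = 0.084, a1 = -0.252, a0 = 6.292,
                        aM = 0.63) {
  out <- numeric(length(A))
  for (i in seq_along(A)) {
    out[i] <- sum(c(a2 * A[i] * A[i], a1 * A[i], a0, aM * M[i]))
  }
  out
}

# Exhaustive maximum-cardinality one-to-one matching between predictions
# and ground truth at an IoU threshold (recursion over gt assignments).
oracle_max_matching <- function(iou, thr) {
  n_pred <- nrow(iou); n_gt <- ncol(iou)
  if (n_pred == 0 || n_gt == 0) return(0L)
  best <- 0L
  recurse <- function(p, used, count) {
    if (count + (n_pred - p + 1L) <= best) return()
    if (p > n_pred) {
      best <<- max(best, count)
      return()
    }
    for (g in seq_len(n_gt)) {
      if (!used[g] && iou[p, g] >= thr) {
        used[g] <- TRUE
        recurse(p + 1L, used, count + 1L)
        used[g] <- FALSE
      }
    }
    recurse(p + 1L, used, count)
  }
  recurse(1L, rep(FALSE, n_gt), 0L)
  best
}

# IoU of two boxes, scalar closed form (independent of bbox_iou()).
oracle_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Count pixels inside a rotated ellipse by scanning pixel centers.
oracle_raster_ellipse_area <- function(cx, cy, a, b, theta, size) {
  count <- 0L
  for (r in seq_len(size)) {
    y <- r - 0.5 - cy
    x <- (seq_len(size) - 0.5) - cx
    u <- cos(theta) * x + sin(theta) * y
    v <- -sin(theta) * x + cos(theta) * y
    count <- count + sum((u / a)^2 + (v / b)^2 <= 1)
  }
  count
}
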