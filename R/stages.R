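# Ripeness stages of the Peruvian commercial standard for camu-camu.
# Order is ripeness order; Green is the only non-commercial stage.
CAMU_STAGES <- c("Green", "Pinton Green", "Ripe Pinton", "Ripe")

#' Ripeness stage labels
#'
#' Camu-camu fruit is staged into four ripeness classes, in ripeness order:
#' Green, Pinton Green, Ripe Pinton, Ripe ("pinton" denotes a turning,
#' intermediate state). Green fruit is non-commercial and is excluded from
#' ascorbate reporting.
#'
#' @return Character vector of the four stage names, in ripeness order.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() CAMU_STAGES

#' @rdname stage_levels
#' @return For `commercial_stages()`, the three commercial stage names
#'   (everything but Green).
#' @export
commercial_stages <- function() CAMU_STAGES[-1L]

# Loose spellings seen in configs/annotations -> canonical stage.
# "Pinton Ripe", "Turn-Ripe" etc. are aliases of "Ripe Pinton"; likewise for
# "Turn-Green".
.stage_alias <- c(
  green        = "Green",
  pintongreen  = "Pinton Green",
  greenpinton  = "Pinton Green",
  turngreen    = "Pinton Green",
  ripepinton   = "Ripe Pinton",
  pintonripe   = "Ripe Pinton",
  turnripe     = "Ripe Pinton",
  ripe         = "Ripe"
)

#' Coerce stage names to the canonical ordered factor
#'
#' Accepts the canonical names plus common variants ("PintonGreen",
#' "Pinton Ripe", "Turn-Green", ...), case- and punctuation-insensitively,
#' and returns an ordered factor over the four canonical levels.
#'
#' @param x Character vector or factor of stage names.
#' @return Ordered factor with levels `stage_levels()`.
#' @export
#' @examples
#' stage_factor(c("ripe", "Pinton Ripe", "Green"))
stage_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (!is.character(x)) abort("stage labels must be character or factor")
  key <- gsub("[^a-z]", "", tolower(x))
  out <- .stage_alias[key]
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(sprintf(
      "unknown ripeness stage(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  factor(unname(out), levels = CAMU_STAGES, ordered = TRUE)
}

#' @rdname stage_factor
#' @return For `stage_ordinal()`, integer ripeness ordinals 0 (Green) to
#'   3 (Ripe).
#' @export
stage_ordinal <- function(x) as.integer(stage_factor(x)) - 1L

#' @rdname stage_factor
#' @return For `is_commercial_stage()`, logical: `TRUE` for every stage but
#'   Green.
#' @export
is_commercial_stage <- function(x) stage_factor(x) != "Green"
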