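# Small, fast scene used by unit tests (320 px canvas, few fruits).
test_scene_spec <- function(n_fruits = 6, seed = 101, ...) {
  scene_spec(image_size_px = 320, n_fruits = n_fruits, seed = seed, ...)
}

# Ground truth reshaped as quantified fruit records, so the expected side
# of end-to-end comparisons can reuse aggregate_image().
gt_as_records <- function(gt) {
  gt$ascorbate_mg_per_100g <- gt$conc_mg_per_100g
  gt$ascorbate_total_mg <- gt$total_mg
  gt$excluded <- gt$stage == "Green"
  gt
}
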