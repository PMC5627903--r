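# Shared fixtures, built once per test run and cached. All synthetic, all
# seeded; sizes chosen small enough for quick unit tests (the acceptance
# tests build full-size study objects themselves).
fixtures <- new.env()

fix_cached <- function(name, build) {
  if (is.null(fixtures[[name]])) fixtures[[name]] <- build()
  fixtures[[name]]
}

fix_cal_spec <- function() {
  fix_cached("cal_spec", function() calibrate_render())
}

# a 3-mm graft with the default dead rim, rendered under calibrated defaults
fix_small_sim <- function() {
  fix_cached("small_sim", function() {
    sim <- simulate_graft(seed = 21, diameter = 3, render = fix_cal_spec())
    sim$mask <- detect_graft_mask(sim$image)
    sim
  })
}

# a high-magnification all-viable field with companion channels
fix_field <- function() {
  fix_cached("field", function() simulate_field(seed = 3,
                                                render = fix_cal_spec()))
}

# nucleus truth coordinates of a simulated field, in cropped-field pixels
field_truth_px <- function(f) {
  n_img <- 1225  # 0.9 mm carrier at 0.8 um/px + 100 px margin
  px <- 0.8
  off <- (n_img - 1) / 2 - floor((n_img - nrow(as.matrix(f$calcein))) / 2)
  tibble::tibble(x = f$truth$nucleus_x_um / px + off,
                 y = f$truth$nucleus_y_um / px + off)
}

# brute-force ROC oracle: explicit double loop over thresholds and patches
roc_oracle <- function(patches, thresholds = 0:255) {
  pos <- patches$mean[patches$label == "viable"]
  neg <- patches$mean[patches$label != "viable"]
  sens <- numeric(length(thresholds))
  spec <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    tp <- 0; tn <- 0
    for (v in pos) if (v > thresholds[k]) tp <- tp + 1
    for (v in neg) if (v <= thresholds[k]) tn <- tn + 1
    sens[k] <- tp / length(pos)
    spec[k] <- tn / length(neg)
  }
  tibble::tibble(threshold = thresholds, sensitivity = sens,
                 specificity = spec)
}
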