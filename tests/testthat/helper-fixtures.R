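# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# 4 cell-type/condition groups x 3 replicate spots, print geometry
# 950/450 um, rasterized at 150 um.
four_group_layout <- function() {
  generate_array_layout(6, 3, pitch_um = 950, spot_diameter_um = 450,
                        groups = c("astro", "neuro", "astroPQ", "astroLS"),
                        standards = c(0, 5, 10))
}

four_group_sim <- function() {
  if (is.null(fixture_env$sim)) {
    lay <- four_group_layout()
    fixture_env$lay <- lay
    fixture_env$sim <- simulate_msi_dataset(lay, synth_config(seed = 11))
  }
  list(layout = fixture_env$lay, dataset = fixture_env$sim$dataset,
       truth = fixture_env$sim$truth)
}

# Foreground = pixels assigned to sample spots; returns TIC-normalized
# spectra plus the matching class labels and spot ids.
foreground_spectra <- function(sim) {
  asn <- assign_pixels(sim$dataset, sim$layout)
  cls <- sim$truth$pixel_class
  fg <- which(!is.na(asn$spot) &
                !(cls %in% c("background", "blank", "standard")))
  list(idx = fg,
       spectra = t(apply(sim$dataset$spectra[fg, , drop = FALSE], 1,
                         tic_normalize)),
       class = cls[fg], spot = asn$spot[fg])
}

# Feature table with enough replicates per group for 10-fold CV:
# 4 groups x 12 replicate spots.
cv_feature_table <- function() {
  if (is.null(fixture_env$ft)) {
    lay <- generate_array_layout(18, 3, groups = c("g1", "g2", "g3", "g4"),
                                 standards = c(0, 5, 10))
    sim <- simulate_msi_dataset(lay, synth_config(seed = 5))
    fixture_env$ft <- spot_feature_table(sim$dataset, lay)
  }
  fixture_env$ft
}

random_spectrum <- function(p = 200) stats::rlnorm(p, log(50), 1)
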