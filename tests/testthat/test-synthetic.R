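zero_effect_config <- function(layout, ...) {
  groups <- unique(layout$sample_label[layout$role == "sample"])
  synth_config(group_effect_log2fc = matrix(0, length(groups), 60,
                                            dimnames = list(groups, NULL)),
               ...)
}

test_that("noiseless simulation reproduces the reference profile exactly", {
  lay <- generate_array_layout(4, 3, groups = c("A", "B"),
                               standards = c(0, 5, 10))
  cfg <- zero_effect_config(lay, tic_cv = 0, noise_sd = 0, seed = 3)
  sim <- simulate_msi_dataset(lay, cfg)
  smp <- sim$truth$pixel_class %in% c("A", "B")
  expect_true(any(smp))
  for (i in which(smp))
    expect_equal(sim$dataset$spectra[i, ], sim$truth$reference_profile)
  # background and blank pixels carry nothing in a noiseless run
  bg <- sim$truth$pixel_class %in% c("background", "blank")
  expect_true(all(sim$dataset$spectra[bg, ] == 0))
})

test_that("identical seed and config give bit-identical datasets", {
  lay <- four_group_layout()
  a <- simulate_msi_dataset(lay, synth_config(seed = 42))
  b <- simulate_msi_dataset(lay, synth_config(seed = 42))
  expect_identical(a$dataset$spectra, b$dataset$spectra)
  expect_identical(a$truth$group_profiles, b$truth$group_profiles)
  c <- simulate_msi_dataset(lay, synth_config(seed = 43))
  expect_false(identical(a$dataset$spectra, c$dataset$spectra))
})

test_that("sample-pixel count equals brute-force disk enumeration", {
  sim <- four_group_sim()
  n_assigned <- sum(!is.na(assign_pixels(sim$dataset, sim$layout)$spot))
  brute <- 0L
  for (i in seq_len(nrow(sim$dataset$coords))) {
    x <- sim$dataset$coords[i, 1]; y <- sim$dataset$coords[i, 2]
    inside <- sqrt((sim$layout$x - x)^2 + (sim$layout$y - y)^2) <=
      sim$layout$diameter / 2
    brute <- brute + as.integer(any(inside))
  }
  expect_equal(n_assigned, brute)
})

test_that("a +/-1 log2 fold change on one feature recovers a 4x spot-mean ratio", {
  groups <- c("up", "down")
  # 50 replicate spots per group: 2 header rows + 34 sample rows of 3
  lay <- generate_array_layout(2 + 34, 3, groups = groups,
                               standards = c(0, 5, 10))
  eff <- matrix(0, 2, 60, dimnames = list(groups, NULL))
  eff["up", 7] <- 1
  eff["down", 7] <- -1
  cfg <- synth_config(group_effect_log2fc = eff, seed = 9)
  sim <- simulate_msi_dataset(lay, cfg)
  asn <- assign_pixels(sim$dataset, lay)
  spot_mean <- function(g) {
    ids <- lay$id[lay$role == "sample" & lay$sample_label == g]
    mean(vapply(ids, function(id)
      mean(sim$dataset$spectra[which(asn$spot == id), 7]), numeric(1)))
  }
  ratio <- spot_mean("up") / spot_mean("down")
  expect_gt(ratio, 4 * 0.9)
  expect_lt(ratio, 4 * 1.1)
})

test_that("outlier injection is an identity at severity 0 and seed-dependent otherwise", {
  sim <- four_group_sim()
  spot <- sim$layout$id[sim$layout$role == "sample"][1]
  expect_identical(
    inject_outlier_replicate(sim$dataset, sim$layout, spot, severity = 0),
    sim$dataset)
  a <- inject_outlier_replicate(sim$dataset, sim$layout, spot, 1, seed = 1)
  b <- inject_outlier_replicate(sim$dataset, sim$layout, spot, 1, seed = 2)
  expect_false(identical(a$spectra, b$spectra))
  expect_error(inject_outlier_replicate(sim$dataset, sim$layout, "nope", 1),
               "unknown spot")
  blank <- sim$layout$id[sim$layout$role == "blank"][1]
  expect_error(inject_outlier_replicate(sim$dataset, sim$layout, blank, 1),
               "not a sample spot")
})

test_that("a fully corrupted replicate is flagged by the r < 0.7 rule", {
  sim <- four_group_sim()
  lay <- sim$layout
  victims <- lay$id[lay$role == "sample" & lay$sample_label == "astro"]
  corrupted <- inject_outlier_replicate(sim$dataset, lay, victims[1], 1,
                                        seed = 4)
  ft <- spot_feature_table(corrupted, lay)
  m <- as.matrix(ft[, grep("^mz_", names(ft))])
  rownames(m) <- ft$spot_id
  rep <- replicate_outliers(m, groups = ft$replicate_group)
  expect_true(victims[1] %in% rep$flagged)
  # and the same array without corruption raises no flags at all
  ft0 <- spot_feature_table(sim$dataset, lay)
  m0 <- as.matrix(ft0[, grep("^mz_", names(ft0))])
  rownames(m0) <- ft0$spot_id
  expect_length(replicate_outliers(m0, groups = ft0$replicate_group)$flagged, 0)
})

test_that("assay scans are linear in amount and reproducible by seed", {
  lay <- generate_array_layout(4, 3, groups = c("A", "B"),
                               standards = c(0, 10, 20))
  cfg <- zero_effect_config(lay, seed = 8)
  sim <- simulate_msi_dataset(lay, cfg)
  img <- simulate_assay_scan(lay, sim$truth, curve_slope = 0.1,
                             curve_intercept = 0.2, noise_sd = 0, seed = 1)
  od <- quantify_spots(img, lay)
  std <- lay$role == "standard"
  expect_equal(unname(od[lay$id[std]]), 0.2 + 0.1 * lay$amount_ng[std])
  expect_equal(unname(od[lay$id[lay$role == "blank"]]), rep(0.2, 3))

  img2 <- simulate_assay_scan(lay, sim$truth, 0.1, 0.2, noise_sd = 0.01,
                              seed = 7)
  img3 <- simulate_assay_scan(lay, sim$truth, 0.1, 0.2, noise_sd = 0.01,
                              seed = 7)
  expect_identical(unclass(img2), unclass(img3))

  curve <- fit_standard_curve(od[lay$id[std]], lay$amount_ng[std])
  expect_equal(curve$slope, 0.1)
  expect_equal(curve$intercept, 0.2)
  expect_equal(curve$r_squared, 1)
})

test_that("assay TIFF round-trip preserves ODs to 16-bit precision", {
  lay <- generate_array_layout(3, 3, groups = "A", standards = c(0, 5, 10))
  sim <- simulate_msi_dataset(lay, zero_effect_config(lay, seed = 2))
  img <- simulate_assay_scan(lay, sim$truth, 0.1, 0.2)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_assay_tiff(img, path, max_od = 4)
  back <- read_assay_tiff(path, max_od = 4,
                          scale_um_per_px = attr(img, "scale"),
                          origin = attr(img, "origin"))
  expect_lt(max(abs(unclass(back) - unclass(img))), 4 / 65535 + 1e-12)
})
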