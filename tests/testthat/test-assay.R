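flat_image <- function(value, n = 120, scale = 25, origin = c(x = -500, y = -500)) {
  structure(matrix(value, n, n), class = "assay_image", scale = scale,
            channel = "Bradford", origin = origin)
}

one_spot <- function(cx = 0, cy = 0) {
  lay <- data.frame(id = "s1", x = cx, y = cy, diameter = 450, role = "sample",
                    sample_label = "A", replicate_group = "A_1",
                    amount_ng = NA_real_)
  attr(lay, "pitch_um") <- 950
  class(lay) <- c("array_layout", "data.frame")
  lay
}

test_that("spot quantification subtracts the annulus background", {
  expect_equal(unname(quantify_spots(flat_image(0.37), one_spot())), 0)

  img <- flat_image(10)
  scale <- attr(img, "scale"); origin <- attr(img, "origin")
  px <- origin["x"] + (seq_len(ncol(img)) - 1) * scale
  py <- origin["y"] + (seq_len(nrow(img)) - 1) * scale
  for (r in seq_along(py)) for (c in seq_along(px))
    if (px[c]^2 + py[r]^2 <= 225^2) img[r, c] <- 100
  expect_equal(unname(quantify_spots(img, one_spot())), 90)

  expect_error(quantify_spots(flat_image(0), one_spot(cx = 5000)),
               "s1")
})

test_that("standard curves fit exactly on exact lines and reject bad input", {
  curve <- fit_standard_curve(c(0.1, 0.6, 1.1, 2.1), c(0, 5, 10, 20))
  expect_equal(curve$slope, 0.1)
  expect_equal(curve$intercept, 0.1)
  expect_equal(curve$r_squared, 1)
  expect_error(fit_standard_curve(c(0.1, 0.6), c(0, 5)), "at least 3")
  expect_error(fit_standard_curve(c(0.1, 0.6, 1), c(5, 5, 5)), "range")
})

test_that("protein estimation inverts the curve and floors at zero", {
  curve <- fit_standard_curve(c(0.1, 0.6, 1.1, 2.1), c(0, 5, 10, 20))
  expect_equal(protein_per_spot(1.6, curve), 15)
  expect_warning(zero <- protein_per_spot(0.05, curve), "floored")
  expect_equal(zero, 0)
  withr::with_seed(17, {
    od <- runif(20, 0.2, 2)
  })
  ng <- protein_per_spot(od, curve)
  expect_equal(curve$intercept + curve$slope * ng, od, tolerance = 1e-9)
})

test_that("activity normalization is raw OD per ng and flags zero protein", {
  expect_equal(normalize_activity(500, 2), 250)
  expect_warning(out <- normalize_activity(c(10, 20), c(5, 0)), "flagged")
  expect_equal(out, c(2, NA))
  expect_equal(normalize_activity(3 * 500, 3 * 2), normalize_activity(500, 2))
})

test_that("deviation-factor bounds flag exactly the hand-computed outliers", {
  none <- deviation_outliers(rep(4.2, 5))
  expect_equal(none$sd, 0)
  expect_false(any(none$flagged))

  v <- c(1, 2, 3, 4, 100)
  db <- deviation_outliers(v, df = 1.25)
  expect_equal(db$mean, 22)
  expect_equal(db$sd, sqrt(7610 / 4))  # sample SD, n - 1
  expect_equal(db$y2, 22 + 1.25 * sqrt(7610 / 4))
  expect_identical(which(db$flagged), 5L)
  expect_equal(db$kept, c(1, 2, 3, 4))

  # symmetry under negation and invariance under positive affine maps
  expect_identical(deviation_outliers(-v)$flagged, db$flagged)
  withr::with_seed(18, {
    w <- rnorm(12)
  })
  base <- deviation_outliers(w)$flagged
  expect_identical(deviation_outliers(3.7 * w + 11)$flagged, base)
  expect_error(deviation_outliers(c(1, 2)), "at least 3")
})

test_that("difference-derived activities subtract per matched spot", {
  total <- data.frame(spot_id = c("a", "b", "c"), activity = c(10, 8, 12))
  bu <- data.frame(spot_id = c("a", "b", "c"), activity = c(4, 8, 2))
  ache <- derived_activity(total, bu)
  expect_equal(ache$activity, c(6, 0, 10))
  # reconstruction on noiseless input
  expect_equal(ache$activity + bu$activity, total$activity)

  expect_warning(derived_activity(total, bu[1:2, ]), "unmatched")
  with_miss <- suppressWarnings(derived_activity(total, bu[1:2, ]))
  expect_equal(with_miss$spot_id, c("a", "b"))
  expect_warning(derived_activity(bu, total), "floored")
})

test_that("group comparison reports ANOVA, Tukey pairs and means", {
  withr::with_seed(19, {
    rec <- data.frame(
      condition = rep(c("ctrl", "stress", "rescue"), each = 6),
      activity = c(rnorm(6, 10), rnorm(6, 10), rnorm(6, 10)))
  })
  same <- group_compare(rec, "one-way", factors = "condition")
  expect_true(all(same$tukey$condition[, "p adj"] > 0.05))

  rec$activity[rec$condition == "stress"] <- rnorm(6, 30, 1)
  diff <- group_compare(rec, "one-way", factors = "condition")
  p <- diff$tukey$condition[, "p adj"]
  expect_lt(p["stress-ctrl"], 0.05)
  expect_lt(p["stress-rescue"], 0.05)
  expect_equal(nrow(diff$group_summary), 3L)

  expect_error(group_compare(rec[rec$condition == "ctrl", ], "one-way",
                             factors = "condition"), "at least 2 groups")

  rec$cell <- rep(c("astro", "neuro"), 9)
  two <- group_compare(rec, "two-way", factors = c("condition", "cell"))
  expect_s3_class(two, "group_comparison")
})

test_that("the full assay chain recovers protein-normalized activities", {
  lay <- generate_array_layout(5, 3, groups = c("A", "B", "C"),
                               standards = c(0, 10, 20))
  sim <- simulate_msi_dataset(lay, synth_config(seed = 23))
  truth <- sim$truth

  # noiseless Bradford scan: generator curve recovered exactly
  bradford <- simulate_assay_scan(lay, truth, 0.08, 0.15, noise_sd = 0)
  od <- quantify_spots(bradford, lay)
  std <- lay$role == "standard"
  curve <- fit_standard_curve(od[lay$id[std]], lay$amount_ng[std])
  expect_equal(curve$slope, 0.08)
  expect_equal(curve$intercept, 0.15)

  # activity channel at 2% noise: OD/ng recovered within 5%
  smp <- lay$id[lay$role == "sample"]
  raw_truth <- truth$activity[smp] * truth$protein_ng[smp]
  act_img <- simulate_assay_scan(lay, truth, 1, 0.1,
                                 noise_sd = 0.02 * mean(raw_truth), seed = 31,
                                 amounts = raw_truth, channel = "NADH")
  brad2 <- simulate_assay_scan(lay, truth, 0.08, 0.15,
                               noise_sd = 0.02 * mean(0.15 + 0.08 * truth$protein_ng[smp]),
                               seed = 32)
  od_act <- quantify_spots(act_img, lay)[smp] - 0.1
  prot <- protein_per_spot(quantify_spots(brad2, lay)[smp], curve)
  recovered <- normalize_activity(od_act, prot)
  expect_true(all(abs(recovered / truth$activity[smp] - 1) < 0.05))
})
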