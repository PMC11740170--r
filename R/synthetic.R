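#' Configuration for the synthetic MSI generator
#'
#' Describes the generative model used to emulate a MALDI-MS imaging run over
#' a printed raft microarray. Each sample group carries a lipid profile equal
#' to a common reference profile modulated by per-feature log2 fold changes;
#' each pixel multiplies its group profile by a log-normal TIC factor
#' (mean 1, coefficient of variation `tic_cv`) and adds Gaussian noise of
#' standard deviation `noise_sd` times the median reference peak height,
#' truncated at zero.
#'
#' @param n_species number of lipid m/z features.
#' @param mz_range two-element m/z interval (Da) the features are drawn from.
#' @param group_effect_log2fc optional groups x features matrix of log2 fold
#'   changes versus the reference profile (rownames are group labels). When
#'   `NULL`, each group receives effects of magnitude `default_effect` on its
#'   own randomly chosen fifth of the features; the affected blocks are kept
#'   disjoint across groups while features last, so every simulated class has
#'   a distinct fingerprint by construction.
#' @param tic_cv coefficient of variation of the per-pixel multiplicative TIC
#'   factor (>= 0).
#' @param noise_sd additive noise scale, relative to the median reference peak
#'   height (>= 0).
#' @param n_replicates_per_sample replicate spots printed per sample (>= 1).
#' @param default_effect magnitude (|log2 fc|) of auto-generated group effects.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical simulated data.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_species = 60, mz_range = c(400, 1000),
                         group_effect_log2fc = NULL,
                         tic_cv = 0.15, noise_sd = 0.02,
                         n_replicates_per_sample = 3,
                         default_effect = 2, seed = 1L) {
  if (n_replicates_per_sample < 1) stopf("n_replicates_per_sample must be >= 1")
  if (tic_cv < 0) stopf("tic_cv must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(mz_range) != 2 || diff(mz_range) <= 0) stopf("mz_range must be an increasing interval")
  structure(list(n_species = as.integer(n_species), mz_range = as.numeric(mz_range),
                 group_effect_log2fc = group_effect_log2fc,
                 tic_cv = tic_cv, noise_sd = noise_sd,
                 n_replicates_per_sample = as.integer(n_replicates_per_sample),
                 default_effect = default_effect, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate an MSI dataset over a printed array
#'
#' Rasterizes the layout at `raster_pitch_um` (the acquisition default is a
#' 150 um grid over 450 um spots at 950 um pitch), covering the bounding box
#' of the spot footprints plus one raster pitch of margin. Pixels whose
#' centres fall inside a sample-spot disk receive that sample's group profile
#' times a per-pixel TIC factor plus truncated Gaussian noise; standard spots
#' receive the unmodulated reference profile (they emulate a common reference
#' tissue); blank spots and background pixels receive noise only.
#'
#' @param layout an `array_layout`.
#' @param config a `synth_config`.
#' @param raster_pitch_um raster node separation (um), > 0.
#' @return A list with `dataset` (an `msi_dataset`) and `truth` (a
#'   `ground_truth` recording pixel class labels, pixel-to-spot assignment,
#'   group profiles, per-spot true protein (ng) and true activity).
#' @examples
#' lay <- generate_array_layout(4, 3, groups = c("A", "B"))
#' sim <- simulate_msi_dataset(lay, synth_config(seed = 7))
#' sim$dataset
#' @export
simulate_msi_dataset <- function(layout, config, raster_pitch_um = 150) {
  validate_layout(layout)
  stopifnot(inherits(config, "synth_config"))
  if (raster_pitch_um <= 0) stopf("raster_pitch_um must be > 0")

  with_seed(config$seed, {
    p <- config$n_species
    mz <- sort(stats::runif(p, config$mz_range[1], config$mz_range[2]))
    reference <- stats::rlnorm(p, meanlog = log(100), sdlog = 1)

    groups <- unique(layout$sample_label[layout$role == "sample"])
    eff <- config$group_effect_log2fc
    if (is.null(eff)) {
      eff <- matrix(0, length(groups), p, dimnames = list(groups, NULL))
      k <- max(1L, round(p / 5))
      unused <- sample.int(p)  # disjoint blocks keep classes distinct
      for (g in groups) {
        if (length(unused) >= k) {
          idx <- unused[seq_len(k)]
          unused <- unused[-seq_len(k)]
        } else {
          idx <- sample.int(p, k)
        }
        eff[g, idx] <- sample(c(-1, 1), k, replace = TRUE) * config$default_effect
      }
    } else {
      eff <- as.matrix(eff)
      if (is.null(rownames(eff)) || !all(groups %in% rownames(eff)) || ncol(eff) != p)
        stopf("group_effect_log2fc must be a groups x n_species matrix with group rownames")
    }
    profiles <- sweep(2^eff[groups, , drop = FALSE], 2, reference, `*`)
    rownames(profiles) <- groups

    # raster over footprint bounding box + one pitch margin, nodes on the pitch
    radius <- layout$diameter / 2
    kx <- floor((min(layout$x - radius) - raster_pitch_um) / raster_pitch_um):
          ceiling((max(layout$x + radius) + raster_pitch_um) / raster_pitch_um)
    ky <- floor((min(layout$y - radius) - raster_pitch_um) / raster_pitch_um):
          ceiling((max(layout$y + radius) + raster_pitch_um) / raster_pitch_um)
    coords <- as.matrix(expand.grid(x = kx * raster_pitch_um, y = ky * raster_pitch_um))
    n <- nrow(coords)

    pixel_spot <- match_pixels_to_spots(coords, layout)
    role_of <- stats::setNames(layout$role, layout$id)
    label_of <- stats::setNames(layout$sample_label, layout$id)
    pixel_class <- ifelse(is.na(pixel_spot), "background",
                   ifelse(role_of[pixel_spot] == "sample", label_of[pixel_spot],
                          role_of[pixel_spot]))

    noise_scale <- config$noise_sd * stats::median(reference)
    sigma2 <- log(1 + config$tic_cv^2)
    tic_factor <- if (config$tic_cv > 0)
      stats::rlnorm(n, meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
    else rep(1, n)

    spectra <- matrix(0, n, p)
    for (i in seq_len(n)) {
      base <- if (pixel_class[i] == "background" || pixel_class[i] == "blank") {
        rep(0, p)
      } else if (pixel_class[i] == "standard") {
        reference * tic_factor[i]
      } else {
        profiles[pixel_class[i], ] * tic_factor[i]
      }
      noise <- if (noise_scale > 0) stats::rnorm(p, 0, noise_scale) else 0
      spectra[i, ] <- pmax(base + noise, 0)
    }

    # latent per-spot protein / activity used by the assay-scan simulator
    protein <- stats::setNames(rep(0, nrow(layout)), layout$id)
    activity <- stats::setNames(rep(0, nrow(layout)), layout$id)
    std <- layout$role == "standard"
    protein[std] <- layout$amount_ng[std]
    smp <- which(layout$role == "sample")
    if (length(smp)) {
      protein[smp] <- stats::rlnorm(length(smp), meanlog = log(15), sdlog = 0.2)
      group_act <- stats::setNames(stats::runif(length(groups), 5, 50), groups)
      activity[smp] <- group_act[layout$sample_label[smp]] *
        stats::rlnorm(length(smp), 0, 0.05)
    }

    truth <- structure(list(pixel_class = pixel_class, pixel_spot = pixel_spot,
                            reference_profile = reference, group_profiles = profiles,
                            group_effect_log2fc = eff, mz = mz,
                            protein_ng = protein, activity = activity),
                       class = "ground_truth")
    dataset <- msi_dataset(coords, mz, spectra, raster_pitch_um)
    list(dataset = dataset, truth = truth)
  })
}

#' Corrupt one replicate spot to create a known outlier
#'
#' Blends each pixel spectrum of the chosen sample spot with a feature-wise
#' permutation of itself: `(1 - severity) * s + severity * s[perm]`. At
#' severity 1 the spot's lipid fingerprint is fully scrambled, so its
#' representative spectrum decorrelates from its sibling replicates and is
#' flagged by the replicate-correlation rule (r < 0.7).
#'
#' @param dataset an `msi_dataset` on a shared axis.
#' @param layout the matching `array_layout`.
#' @param spot_id id of a sample spot to corrupt.
#' @param severity blending fraction in \[0, 1\]; 0 leaves the data unchanged.
#' @param seed integer seed controlling the permutation.
#' @return The modified `msi_dataset`.
#' @export
inject_outlier_replicate <- function(dataset, layout, spot_id, severity, seed = 1L) {
  stopifnot(inherits(dataset, "msi_dataset"), is_continuous(dataset))
  if (severity < 0 || severity > 1) stopf("severity must be in [0, 1]")
  i <- match(spot_id, layout$id)
  if (is.na(i)) stopf("unknown spot id '%s'", spot_id)
  if (layout$role[i] != "sample") stopf("spot '%s' is not a sample spot", spot_id)
  if (severity == 0) return(dataset)
  pix <- which(match_pixels_to_spots(dataset$coords, layout) == spot_id)
  with_seed(seed, {
    perm <- sample.int(ncol(dataset$spectra))
    dataset$spectra[pix, ] <- (1 - severity) * dataset$spectra[pix, , drop = FALSE] +
      severity * dataset$spectra[pix, perm, drop = FALSE]
  })
  dataset
}

#' Simulate a scanned assay image
#'
#' Renders a grayscale scan of the array in which the intensity inside each
#' spot footprint is linear in the analyte amount: `intercept + slope *
#' amount`, over a zero background, plus independent Gaussian read noise of
#' standard deviation `noise_sd` on every image pixel (the whole frame is
#' floored at 0). Blank spots carry amount 0 and thus sit at `intercept +
#' noise`. By default the amount is the true immobilized protein (a Bradford
#' scan); pass `amounts` to render any other channel.
#'
#' @param layout an `array_layout`.
#' @param truth the `ground_truth` from [simulate_msi_dataset()].
#' @param curve_slope optical density per ng (> 0).
#' @param curve_intercept optical density at zero amount.
#' @param noise_sd standard deviation of the per-pixel OD read noise.
#' @param seed integer seed.
#' @param scale_um_per_px image resolution (um per pixel).
#' @param channel channel label, e.g. `"Bradford"`, `"NADH"`, `"ChE"`.
#' @param amounts optional named per-spot amounts overriding the Bradford
#'   default (`truth$protein_ng`).
#' @return An `assay_image`: the intensity matrix with attributes `scale`
#'   (um/px), `channel`, `origin` (um of pixel (1,1) centre) and the
#'   generating `slope`/`intercept`.
#' @export
simulate_assay_scan <- function(layout, truth, curve_slope, curve_intercept,
                                noise_sd = 0, seed = 1L, scale_um_per_px = 25,
                                channel = "Bradford", amounts = NULL) {
  validate_layout(layout)
  if (curve_slope <= 0) stopf("curve_slope must be > 0")
  if (is.null(amounts)) amounts <- truth$protein_ng
  amounts[layout$id[layout$role == "blank"]] <- 0
  std <- layout$role == "standard"
  amounts[layout$id[std]] <- layout$amount_ng[std]

  radius <- layout$diameter / 2
  margin <- attr(layout, "pitch_um")
  if (!is.finite(margin)) margin <- max(layout$diameter)
  x0 <- min(layout$x - radius) - margin
  y0 <- min(layout$y - radius) - margin
  nx <- ceiling((max(layout$x + radius) + margin - x0) / scale_um_per_px) + 1L
  ny <- ceiling((max(layout$y + radius) + margin - y0) / scale_um_per_px) + 1L
  img <- matrix(0, nrow = ny, ncol = nx)  # row = y, col = x
  px <- x0 + (seq_len(nx) - 1) * scale_um_per_px
  py <- y0 + (seq_len(ny) - 1) * scale_um_per_px

  with_seed(seed, {
    for (i in seq_len(nrow(layout))) {
      od <- curve_intercept + curve_slope * amounts[layout$id[i]]
      cols <- which(abs(px - layout$x[i]) <= radius[i])
      rows <- which(abs(py - layout$y[i]) <= radius[i])
      for (r in rows) {
        inside <- dist2(px[cols], py[r], layout$x[i], layout$y[i]) <= radius[i]^2
        img[r, cols[inside]] <- od
      }
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          nrow(img), ncol(img))
    img <- pmax(img, 0)
  })
  structure(img, class = "assay_image", scale = scale_um_per_px,
            channel = channel, origin = c(x = x0, y = y0),
            slope = curve_slope, intercept = curve_intercept)
}

#' @export
print.assay_image <- function(x, ...) {
  cat(sprintf("Assay image (%s): %d x %d px at %g um/px, OD range [%.3g, %.3g]\n",
              attr(x, "channel"), nrow(x), ncol(x), attr(x, "scale"),
              min(x), max(x)))
  invisible(x)
}

#' Write / read an assay image as 16-bit grayscale TIFF
#'
#' Optical densities are stored as `od / max_od` in 16-bit samples, so values
#' survive a round trip to within `max_od / 65535`.
#'
#' @param image an `assay_image`.
#' @param path file path.
#' @param max_od full-scale OD mapped to the maximum 16-bit sample.
#' @return `read_assay_tiff` returns an `assay_image`.
#' @export
write_assay_tiff <- function(image, path, max_od = 4) {
  m <- pmin(pmax(unclass(image) / max_od, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_assay_tiff
#' @param scale_um_per_px,channel,origin metadata to attach on read (TIFF
#'   carries none).
#' @export
read_assay_tiff <- function(path, max_od = 4, scale_um_per_px = 25,
                            channel = "Bradford", origin = c(x = 0, y = 0)) {
  m <- tiff::readTIFF(path) * max_od
  structure(m, class = "assay_image", scale = scale_um_per_px,
            channel = channel, origin = origin)
}
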