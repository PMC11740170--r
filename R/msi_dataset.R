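#' Construct an MSI dataset
#'
#' Container for a mass-spectrometry imaging raster. Two axis modes are
#' supported, mirroring imzML: *continuous* (all pixels share one m/z axis;
#' `mz` is a numeric vector and `spectra` an n-pixel x n-feature matrix) and
#' *processed* (per-pixel axes; `mz` and `spectra` are lists of numeric
#' vectors). Coordinates are in micrometres, origin at the top-left spot
#' centre, x growing right and y growing down, and must sit on the stated
#' raster pitch.
#'
#' @param coords n x 2 numeric matrix of pixel centres (um), columns x, y.
#' @param mz shared m/z axis (strictly increasing numeric vector) or a list of
#'   per-pixel axes.
#' @param spectra intensity matrix (pixels x features) or list of intensity
#'   vectors; intensities must be non-negative.
#' @param raster_pitch_um raster node separation in um.
#' @param ion_mode `"negative"` or `"positive"`.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, spectra, raster_pitch_um,
                        ion_mode = c("negative", "positive")) {
  ion_mode <- match.arg(ion_mode)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stopf("coords must have two columns (x, y)")
  colnames(coords) <- c("x", "y")
  if (anyDuplicated(paste(coords[, 1], coords[, 2])))
    stopf("pixel coordinates must be unique")
  if (is.list(mz)) {
    if (!is.list(spectra) || length(mz) != nrow(coords) ||
        length(spectra) != nrow(coords))
      stopf("processed mode: mz and spectra must be lists of length nrow(coords)")
    for (i in seq_along(mz)) {
      if (length(mz[[i]]) != length(spectra[[i]]))
        stopf("pixel %d: axis and intensity lengths differ", i)
      if (is.unsorted(mz[[i]], strictly = TRUE)) stopf("pixel %d: m/z axis not strictly increasing", i)
      if (any(spectra[[i]] < 0)) stopf("pixel %d: negative intensities", i)
    }
    mode <- "processed"
  } else {
    spectra <- as.matrix(spectra)
    if (nrow(spectra) != nrow(coords) || ncol(spectra) != length(mz))
      stopf("spectra must be nrow(coords) x length(mz)")
    if (is.unsorted(mz, strictly = TRUE)) stopf("m/z axis must be strictly increasing")
    if (any(mz <= 0)) stopf("m/z values must be positive")
    if (any(spectra < 0)) stopf("intensities must be non-negative")
    mode <- "continuous"
  }
  structure(list(coords = coords, mz = mz, spectra = spectra,
                 raster_pitch = raster_pitch_um, ion_mode = ion_mode,
                 mode = mode),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  nf <- if (x$mode == "continuous") length(x$mz) else
    sprintf("%d-%d (per pixel)", min(lengths(x$mz)), max(lengths(x$mz)))
  cat(sprintf("MSI dataset: %d pixels, %s m/z features, %s mode, %s ion mode, %g um raster\n",
              nrow(x$coords), paste(nf, collapse = ""), x$mode, x$ion_mode,
              x$raster_pitch))
  invisible(x)
}

n_pixels <- function(dataset) nrow(dataset$coords)

is_continuous <- function(dataset) dataset$mode == "continuous"

# Raw TIC per pixel.
pixel_tic <- function(dataset) {
  if (is_continuous(dataset)) rowSums(dataset$spectra)
  else vapply(dataset$spectra, sum, numeric(1))
}

# Spot id (or NA) for each pixel centre: inclusive disk membership.
# Shared by the generator and the spot-summary module.
match_pixels_to_spots <- function(coords, layout) {
  validate_layout(layout)
  n <- nrow(coords)
  out <- rep(NA_character_, n)
  for (i in seq_len(nrow(layout))) {
    r2 <- (layout$diameter[i] / 2)^2
    inside <- dist2(coords[, 1], coords[, 2], layout$x[i], layout$y[i]) <= r2
    clash <- inside & !is.na(out)
    if (any(clash))
      stopf("overlapping spot footprints: pixel at (%g, %g) falls in spots %s and %s",
            coords[which(clash)[1], 1], coords[which(clash)[1], 2],
            out[which(clash)[1]], layout$id[i])
    out[inside] <- layout$id[i]
  }
  out
}
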