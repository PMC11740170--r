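#' TIC-normalize a spectrum
#'
#' Divides intensities by their sum (the total ion current), so the output
#' sums to 1. This removes pixel-to-pixel variation in deposited material and
#' laser coupling before spectra are compared.
#'
#' @param intensities non-negative intensity vector with at least one
#'   positive value.
#' @return The normalized intensity vector.
#' @examples
#' tic_normalize(c(2, 3, 5))
#' @export
tic_normalize <- function(intensities) {
  s <- sum(intensities)
  if (s <= 0) stopf("empty spectrum: total ion current is zero")
  intensities / s
}

# TIC-normalize every row of a pixel x feature matrix.
tic_normalize_rows <- function(m) {
  s <- rowSums(m)
  if (any(s <= 0)) stopf("empty spectrum: total ion current is zero for %d pixel(s)",
                         sum(s <= 0))
  m / s
}

#' Align spectra onto a shared m/z axis by binning
#'
#' Pools the peaks of all pixels, sorts them by m/z, and groups them wherever
#' consecutive peaks are within `bin_width_da` of each other (single-linkage
#' gap grouping, so peaks straddling an arbitrary bin edge still merge). Each
#' pixel's intensities within a group are summed, and the shared axis takes
#' each group's intensity-weighted mean m/z. Per-pixel total intensity is
#' conserved exactly, and a dataset whose axis gaps all exceed the bin width
#' comes back with values unchanged.
#'
#' @param dataset an `msi_dataset` (continuous or processed mode).
#' @param bin_width_da maximum m/z gap within one feature, in Da (> 0);
#'   default 0.01.
#' @return A continuous-mode `msi_dataset` on the shared binned axis.
#' @export
align_spectra <- function(dataset, bin_width_da = 0.01) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (bin_width_da <= 0) stopf("bin width must be > 0")
  n <- n_pixels(dataset)
  mz_list <- if (is_continuous(dataset)) rep(list(dataset$mz), n) else dataset$mz
  int_list <- if (is_continuous(dataset))
    lapply(seq_len(n), function(i) dataset$spectra[i, ]) else dataset$spectra

  all_mz <- unlist(mz_list, use.names = FALSE)
  all_int <- unlist(int_list, use.names = FALSE)
  pix <- rep.int(seq_len(n), lengths(mz_list))
  o <- order(all_mz)
  bidx <- integer(length(all_mz))
  bidx[o] <- cumsum(c(1L, diff(all_mz[o]) > bin_width_da))
  nb <- max(bidx)

  wsum <- unname(rowsum(all_int, bidx)[, 1])
  msum <- unname(rowsum(all_mz * all_int, bidx)[, 1])
  counts <- tabulate(bidx, nb)
  centre <- ifelse(wsum > 0, msum / wsum,
                   unname(rowsum(all_mz, bidx)[, 1]) / counts)

  spectra <- matrix(0, n, nb)
  for (k in seq_along(all_mz))
    spectra[pix[k], bidx[k]] <- spectra[pix[k], bidx[k]] + all_int[k]

  msi_dataset(dataset$coords, unname(centre), spectra,
              dataset$raster_pitch, dataset$ion_mode)
}

#' Filter peaks below a fraction of the base peak
#'
#' Zeroes every intensity strictly below `threshold_fraction` times the
#' spectrum's maximum (default 0.5% of the strongest peak). Values exactly at
#' the threshold are retained, and the base peak always survives.
#'
#' @param intensities intensity vector with at least one positive value.
#' @param threshold_fraction relative threshold in (0, 1); default 0.005.
#' @return The filtered intensity vector.
#' @examples
#' peak_filter(c(1000, 100, 4))   # 4 < 5 is dropped
#' @export
peak_filter <- function(intensities, threshold_fraction = 0.005) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stopf("threshold_fraction must be in (0, 1)")
  mx <- max(intensities)
  if (mx <= 0) stopf("empty spectrum: no positive intensity")
  ifelse(intensities < threshold_fraction * mx, 0, intensities)
}

#' Annotate peaks against a lipid m/z table
#'
#' Matches each peak to the nearest annotation within a ppm tolerance and a
#' matching ion mode; peaks with no annotation in range keep an empty
#' annotation.
#'
#' @param peaks data frame with columns `mz` and optionally `ion_mode`.
#' @param annotations data frame with columns `mz`, `species`, `adduct`,
#'   `ion_mode`.
#' @param tol_ppm matching tolerance in parts per million (> 0).
#' @param ion_mode ion mode of the peaks when `peaks` carries no such column.
#' @return `peaks` with added `species` and `adduct` columns (`NA` where
#'   unmatched) and `match_ppm`, the signed ppm error of the match.
#' @export
annotate_peaks <- function(peaks, annotations, tol_ppm = 5,
                           ion_mode = "negative") {
  if (tol_ppm <= 0) stopf("tol_ppm must be > 0")
  peaks <- as.data.frame(peaks)
  peaks$species <- NA_character_
  peaks$adduct <- NA_character_
  peaks$match_ppm <- NA_real_
  if (is.null(annotations) || !nrow(annotations)) return(peaks)
  pk_mode <- if ("ion_mode" %in% names(peaks)) peaks$ion_mode else
    rep(ion_mode, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cand <- annotations[annotations$ion_mode == pk_mode[i], , drop = FALSE]
    if (!nrow(cand)) next
    ppm <- (peaks$mz[i] - cand$mz) / cand$mz * 1e6
    j <- which.min(abs(ppm))
    if (abs(ppm[j]) <= tol_ppm) {
      peaks$species[i] <- cand$species[j]
      peaks$adduct[i] <- cand$adduct[j]
      peaks$match_ppm[i] <- ppm[j]
    }
  }
  peaks
}

#' Flag replicate outliers by Pearson correlation
#'
#' Within each replicate group, every member's Pearson r against each sibling
#' is computed on the shared axis. Outliers are pruned iteratively: while any
#' member's median correlation with its current siblings falls strictly below
#' the threshold (default 0.7; r of exactly 0.7 is kept), the worst such
#' member is flagged and removed, and medians are recomputed. The iteration
#' keeps one corrupted replicate from dragging down its clean siblings'
#' medians.
#'
#' @param spectra named list of replicate groups, each a list (or matrix rows)
#'   of spectra on a shared axis, or a matrix plus `groups`.
#' @param groups replicate-group label per spectrum when `spectra` is a
#'   matrix.
#' @param threshold correlation threshold; default 0.7.
#' @return An `outlier_report`: data frame of pairwise correlations
#'   (`group`, `a`, `b`, `r`), the flagged unit ids, per-unit median sibling
#'   correlation, and the threshold used.
#' @export
replicate_outliers <- function(spectra, groups = NULL, threshold = 0.7) {
  if (is.matrix(spectra)) {
    if (is.null(groups) || length(groups) != nrow(spectra))
      stopf("groups must label each row of the spectra matrix")
    ids <- rownames(spectra)
    if (is.null(ids)) ids <- sprintf("unit%02d", seq_len(nrow(spectra)))
    split_idx <- split(seq_len(nrow(spectra)), groups)
    spectra <- lapply(split_idx, function(ix) {
      m <- spectra[ix, , drop = FALSE]; rownames(m) <- ids[ix]; m
    })
  } else {
    spectra <- lapply(spectra, function(g) {
      m <- do.call(rbind, g)
      if (is.null(rownames(m)))
        rownames(m) <- if (!is.null(names(g))) names(g) else
          sprintf("unit%02d", seq_len(nrow(m)))
      m
    })
  }
  pairs <- list(); medians <- list(); flagged <- character()
  for (g in names(spectra)) {
    m <- spectra[[g]]
    if (nrow(m) < 2L) {
      warnf("replicate group '%s' has fewer than 2 members; skipped", g)
      next
    }
    r <- row_cor_matrix(m, warn = FALSE)
    ids <- rownames(m)
    for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m))
      pairs[[length(pairs) + 1L]] <- data.frame(group = g, a = ids[i],
                                                b = ids[j], r = r[i, j])
    med <- vapply(seq_len(nrow(m)),
                  function(i) stats::median(r[i, -i]), numeric(1))
    names(med) <- ids
    medians[[g]] <- med
    # iterative pruning: drop the worst sub-threshold member, recompute
    alive <- seq_len(nrow(m))
    while (length(alive) >= 2L) {
      cur <- vapply(alive, function(i)
        stats::median(r[i, setdiff(alive, i)]), numeric(1))
      if (min(cur) >= threshold) break
      if (length(alive) == 2L) {
        # a discordant pair cannot be arbitrated: neither is trusted
        flagged <- c(flagged, ids[alive])
        alive <- integer()
        break
      }
      worst <- alive[which.min(cur)]
      flagged <- c(flagged, ids[worst])
      alive <- setdiff(alive, worst)
    }
  }
  structure(list(pairs = do.call(rbind, pairs),
                 median_r = unlist(unname(medians)),
                 flagged = flagged, threshold = threshold),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Replicate outlier report (r < %g rule): %d unit(s) flagged\n",
              x$threshold, length(x$flagged)))
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
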