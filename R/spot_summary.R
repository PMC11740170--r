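#' Assign raster pixels to printed spots
#'
#' A pixel belongs to a spot iff its centre lies within the spot's disk
#' (inclusive boundary). With the default print geometry (950 um pitch,
#' 450 um diameter) the disks are disjoint, so each pixel has at most one
#' spot; overlapping footprints raise an error.
#'
#' @param dataset an `msi_dataset`.
#' @param layout an `array_layout` in the same coordinate frame.
#' @return A `spot_assignment`: list with `spot` (per-pixel spot id, `NA` for
#'   background) and `counts` (pixels per spot).
#' @export
assign_pixels <- function(dataset, layout) {
  stopifnot(inherits(dataset, "msi_dataset"))
  spot <- match_pixels_to_spots(dataset$coords, layout)
  counts <- table(factor(spot, levels = layout$id))
  structure(list(spot = spot, counts = counts), class = "spot_assignment")
}

#' @export
print.spot_assignment <- function(x, ...) {
  cat(sprintf("Spot assignment: %d/%d pixels on spots (per-spot range %d-%d)\n",
              sum(!is.na(x$spot)), length(x$spot), min(x$counts), max(x$counts)))
  invisible(x)
}

#' Representative spectrum of a spot by divisive clustering
#'
#' The pixels of one spot are divisively partitioned — using the same
#' walker-competition split as the whole-array segmentation — until every
#' segment is internally coherent (all pairwise Pearson r strictly above
#' `r_threshold`, default 0.9). The most intense segment, i.e. the one with
#' the largest summed raw TIC (ties broken by larger pixel count, then
#' lowest pixel index), is selected and its mean TIC-normalized spectrum
#' returned as the spot's representative.
#'
#' @param spectra pixel x feature matrix of the spot's raw spectra (>= 1
#'   pixel, shared axis).
#' @param r_threshold pairwise-correlation coherence requirement.
#' @return A `spot_spectrum`: list with `spectrum` (TIC-normalized, sums to
#'   1), `segment_sizes` of all segments found, `chosen` (index of the
#'   selected segment), `members` (pixel indices of the chosen segment) and
#'   `cohesion` (min pairwise r within it; 1 for a single pixel).
#' @export
representative_spectrum <- function(spectra, r_threshold = 0.9) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (n < 1L) stopf("empty pixel list")
  if (n == 1L) {
    return(structure(list(spectrum = tic_normalize(spectra[1, ]),
                          segment_sizes = 1L, chosen = 1L, members = 1L,
                          cohesion = 1),
                     class = "spot_spectrum"))
  }
  tm <- build_transition(spectra)
  r <- attr(tm, "correlation")
  segments <- list(seq_len(n))
  repeat {
    minr <- vapply(segments, function(s) min_pairwise_r(r, s), numeric(1))
    bad <- which(lengths(segments) >= 2L & minr <= r_threshold)
    if (!length(bad)) break
    worst <- bad[which.min(minr[bad])]
    halves <- rankcompete_split(tm, segments[[worst]])
    segments <- c(segments[-worst], halves)
  }
  segments <- segments[order(vapply(segments, min, integer(1)))]

  tic <- rowSums(spectra)
  score <- vapply(segments, function(s) sum(tic[s]), numeric(1))
  sizes <- lengths(segments)
  best <- order(-score, -sizes, vapply(segments, min, integer(1)))[1L]
  members <- segments[[best]]
  norm <- t(apply(spectra[members, , drop = FALSE], 1L, tic_normalize))
  structure(list(spectrum = colMeans(norm), segment_sizes = sizes,
                 chosen = best, members = members,
                 cohesion = min_pairwise_r(r, members)),
            class = "spot_spectrum")
}

#' Per-spot lipid feature table
#'
#' Runs [assign_pixels()] and [representative_spectrum()] over every spot of
#' the requested roles and assembles the spots x features matrix of
#' TIC-normalized representative intensities that feeds ranking, PCA and the
#' classifiers.
#'
#' @param dataset a continuous-mode `msi_dataset` (align first if needed).
#' @param layout an `array_layout`.
#' @param roles spot roles to include (default samples only).
#' @param r_threshold passed to [representative_spectrum()].
#' @param min_pixels spots with fewer assigned pixels are dropped with a
#'   warning.
#' @return A `feature_table` (data frame with `spot_id`, `group`,
#'   `replicate_group`, then one `mz_*` column per feature), with the
#'   per-spot provenance (segment sizes, cohesion) in
#'   `attr(, "provenance")`.
#' @export
spot_feature_table <- function(dataset, layout, roles = "sample",
                               r_threshold = 0.9, min_pixels = 1L) {
  stopifnot(is_continuous(dataset))
  assignment <- assign_pixels(dataset, layout)
  keep <- layout[layout$role %in% roles, , drop = FALSE]
  rows <- list(); prov <- list()
  for (i in seq_len(nrow(keep))) {
    id <- keep$id[i]
    pix <- which(assignment$spot == id)
    if (length(pix) < min_pixels) {
      warnf("spot %s has %d pixel(s) (< %d); dropped", id, length(pix), min_pixels)
      next
    }
    rep_sp <- representative_spectrum(dataset$spectra[pix, , drop = FALSE],
                                      r_threshold)
    rows[[id]] <- rep_sp$spectrum
    prov[[id]] <- list(n_pixels = length(pix),
                       segment_sizes = rep_sp$segment_sizes,
                       cohesion = rep_sp$cohesion)
  }
  if (!length(rows)) stopf("no spot had >= %d pixels", min_pixels)
  x <- do.call(rbind, rows)
  colnames(x) <- sprintf("mz_%.4f", dataset$mz)
  ids <- names(rows)
  meta <- keep[match(ids, keep$id), ]
  ft <- data.frame(spot_id = ids,
                   group = ifelse(is.na(meta$sample_label), meta$role,
                                  meta$sample_label),
                   replicate_group = meta$replicate_group,
                   stringsAsFactors = FALSE)
  ft <- cbind(ft, as.data.frame(x))
  rownames(ft) <- NULL
  attr(ft, "provenance") <- prov
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Coerce a data frame to a feature table
#'
#' @param df a data frame with `spot_id` and `group` columns followed by
#'   numeric feature columns.
#' @export
as_feature_table <- function(df) {
  if (!all(c("spot_id", "group") %in% names(df)))
    stopf("a feature table needs 'spot_id' and 'group' columns")
  if (anyDuplicated(names(df))) stopf("feature column names must be unique")
  if (anyNA(df$group)) stopf("missing group labels")
  class(df) <- c("feature_table", "data.frame")
  df
}

# Numeric feature matrix / group labels of a feature table.
ft_matrix <- function(ft) {
  meta <- intersect(c("spot_id", "group", "replicate_group"), names(ft))
  m <- as.matrix(ft[, setdiff(names(ft), meta), drop = FALSE])
  rownames(m) <- ft$spot_id
  m
}

ft_groups <- function(ft) factor(ft$group)
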