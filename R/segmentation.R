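#' Build the random-walk transition matrix over pixel spectra
#'
#' The walker competition operates on a Markov chain whose states are pixels.
#' The affinity between two pixels is `(1 + r) / 2`, with `r` their Pearson
#' correlation — a monotone map of similarity onto \[0, 1\] that keeps the
#' chain irreducible except at perfect anti-correlation. The diagonal is zero
#' before normalization and each row is scaled to sum to one. A
#' zero-variance spectrum has its correlations defined as 0 (affinity 1/2),
#' with a warning.
#'
#' @param spectra n x p matrix, one spectrum per row, shared axis, n >= 2.
#' @return A row-stochastic n x n matrix of class `transition_matrix`, with
#'   the pixel correlation matrix attached as `attr(, "correlation")`.
#' @export
build_transition <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2L) stopf("need at least 2 spectra")
  r <- row_cor_matrix(spectra)
  a <- (1 + r) / 2
  diag(a) <- 0
  tm <- normalize_rows(a)
  structure(tm, class = "transition_matrix", correlation = r)
}

# Scale rows to sum 1; an all-zero row (a node with zero affinity to every
# other) becomes uniform over the remaining nodes so the chain stays defined.
normalize_rows <- function(a) {
  s <- rowSums(a)
  dead <- s == 0
  if (any(dead)) {
    n <- ncol(a)
    a[dead, ] <- 1 / (n - 1)
    diag(a)[dead] <- 0
    s[dead] <- rowSums(a[dead, , drop = FALSE])
  }
  a / s
}

# Personalized rank of a restarting walker seeded at `seed`, by power
# iteration of v <- (1 - restart) * t(T) v + restart * e_seed.
personalized_rank <- function(tm, seed, restart = 0.15, tol = 1e-10,
                              max_iter = 10000L) {
  n <- nrow(tm)
  e <- numeric(n); e[seed] <- 1
  v <- e
  tt <- t(tm)
  for (it in seq_len(max_iter)) {
    v_new <- (1 - restart) * drop(tt %*% v) + restart * e
    res <- max(abs(v_new - v))
    v <- v_new
    if (res < tol) return(v)
  }
  stopf("walker rank iteration did not converge in %d steps (residual %.3g)",
        max_iter, res)
}

#' Split a segment by competing random walkers
#'
#' Two walkers are seeded at the least-correlated pixel pair within the
#' segment. Each walker's personalized rank vector is the stationary solution
#' of a restarting random walk on the segment's sub-chain (rows restricted to
#' the segment and renormalized). Every pixel joins the walker that ranks it
#' higher; rank ties go to the walker whose seed has the lower index, and
#' each seed always belongs to its own walker, so both halves are non-empty.
#'
#' @param transition a `transition_matrix` from [build_transition()] over all
#'   pixels.
#' @param members integer indices (into the transition matrix) of the
#'   segment's pixels, length >= 2.
#' @param restart restart probability of the walk (default 0.15).
#' @param tol convergence tolerance on the rank vector (sup norm).
#' @param max_iter maximum power-iteration count.
#' @return A list of two integer vectors, the member indices of each half.
#' @export
rankcompete_split <- function(transition, members, restart = 0.15,
                              tol = 1e-10, max_iter = 10000L) {
  if (length(members) < 2L) stopf("segment must have at least 2 pixels")
  r <- attr(transition, "correlation")
  if (is.null(r)) stopf("transition matrix lacks its correlation attribute")
  if (length(members) == 2L)
    return(list(members[1L], members[2L]))
  sub_r <- r[members, members, drop = FALSE]
  sub_a <- unclass(transition)[members, members, drop = FALSE]
  sub_t <- normalize_rows(sub_a)

  # seeds: least-correlated pair, first in column-major order on ties
  m <- length(members)
  sub_r[upper.tri(sub_r, diag = TRUE)] <- Inf
  ij <- arrayInd(which.min(sub_r), dim(sub_r))
  s1 <- min(ij); s2 <- max(ij)

  v1 <- personalized_rank(sub_t, s1, restart, tol, max_iter)
  v2 <- personalized_rank(sub_t, s2, restart, tol, max_iter)
  to_first <- v1 > v2 | (v1 == v2 & s1 < s2)
  to_first[s1] <- TRUE
  to_first[s2] <- FALSE
  list(members[to_first], members[!to_first])
}

mean_pairwise_r <- function(r, members) {
  if (length(members) < 2L) return(1)
  sub <- r[members, members]
  mean(sub[lower.tri(sub)])
}

min_pairwise_r <- function(r, members) {
  if (length(members) < 2L) return(1)
  sub <- r[members, members]
  min(sub[lower.tri(sub)])
}

#' Segment pixel spectra by divisive analysis with walker competition
#'
#' Top-down segmentation of an imaging experiment: starting from a single
#' segment holding every foreground pixel, the algorithm repeatedly selects
#' the least coherent segment — lowest mean internal pairwise correlation —
#' among those still splittable (at least `min_size` pixels, cohesion below
#' `cohesion_stop`) and divides it in two with [rankcompete_split()]. The
#' result is a partition of the pixels; no randomness is involved, so
#' identical input gives an identical segmentation.
#'
#' @param spectra n x p matrix of (typically TIC-normalized) pixel spectra.
#' @param cohesion_stop stop splitting a segment once its mean internal
#'   pairwise correlation reaches this value (default 0.9).
#' @param min_size segments smaller than this are never split (default 3).
#' @param max_segments hard cap on the number of segments.
#' @param restart,tol,max_iter passed to [rankcompete_split()].
#' @return A `segmentation`: list with `segments` (pixel index sets),
#'   `labels` (per-pixel segment number), `mean_spectra`, `cohesion` (mean
#'   internal pairwise r per segment), and after [color_segments()] also
#'   `positions` and `colors`.
#' @examples
#' x <- rbind(matrix(rep(c(5, 1, 1), 4), 4, byrow = TRUE) + 0.01 * 1:4,
#'            matrix(rep(c(1, 5, 1), 4), 4, byrow = TRUE) + 0.01 * 1:4)
#' seg <- diana_rankcompete(x, cohesion_stop = 0.9)
#' seg$labels
#' @export
diana_rankcompete <- function(spectra, cohesion_stop = 0.9, min_size = 3L,
                              max_segments = Inf, restart = 0.15,
                              tol = 1e-10, max_iter = 10000L) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (n < 1L) stopf("need at least 1 foreground pixel")
  if (n == 1L) {
    seg <- list(segments = list(1L), labels = 1L,
                mean_spectra = matrix(tic_normalize(spectra[1, ]), 1),
                cohesion = 1)
    class(seg) <- "segmentation"
    return(seg)
  }
  tm <- build_transition(spectra)
  r <- attr(tm, "correlation")

  segments <- list(seq_len(n))
  repeat {
    cohesion <- vapply(segments, function(s) mean_pairwise_r(r, s), numeric(1))
    eligible <- which(lengths(segments) >= min_size & cohesion < cohesion_stop)
    if (!length(eligible) || length(segments) >= max_segments) break
    worst <- eligible[which.min(cohesion[eligible])]
    halves <- rankcompete_split(tm, segments[[worst]], restart, tol, max_iter)
    segments <- c(segments[-worst], halves)
  }
  # deterministic ordering: by smallest member index
  segments <- segments[order(vapply(segments, min, integer(1)))]

  labels <- integer(n)
  for (k in seq_along(segments)) labels[segments[[k]]] <- k
  norm <- tic_normalize_rows(pmax(spectra, 0) + 1e-300)
  mean_spectra <- do.call(rbind, lapply(segments, function(s)
    colMeans(norm[s, , drop = FALSE])))
  cohesion <- vapply(segments, function(s) mean_pairwise_r(r, s), numeric(1))
  structure(list(segments = segments, labels = labels,
                 mean_spectra = mean_spectra, cohesion = cohesion),
            class = "segmentation")
}

#' Place segments on a correlation-based color scale
#'
#' The two segments whose mean spectra are least correlated define the
#' extremes of the scale (positions 0 and 1); every other segment sits at
#' `d(A, C) / (d(A, C) + d(C, B))` with `d = 1 - r`, so segments with similar
#' average spectra receive nearby colors. Positions are mapped onto a rainbow
#' scale. A single segment sits at 0.5.
#'
#' @param segmentation a `segmentation` from [diana_rankcompete()].
#' @return The segmentation with `positions` (in \[0, 1\]), `colors` (hex)
#'   and `segment_correlation` (k x k matrix of mean-spectrum correlations)
#'   added.
#' @export
color_segments <- function(segmentation) {
  stopifnot(inherits(segmentation, "segmentation"))
  k <- length(segmentation$segments)
  if (k == 1L) {
    segmentation$positions <- 0.5
    segmentation$segment_correlation <- matrix(1, 1, 1)
  } else {
    r <- row_cor_matrix(segmentation$mean_spectra, warn = FALSE)
    d <- 1 - r
    rl <- r
    rl[upper.tri(rl, diag = TRUE)] <- Inf
    ij <- arrayInd(which.min(rl), dim(rl))
    a <- min(ij); b <- max(ij)
    pos <- vapply(seq_len(k), function(ci) {
      if (ci == a) return(0)
      if (ci == b) return(1)
      da <- d[a, ci]; db <- d[ci, b]
      if (da + db == 0) 0.5 else da / (da + db)
    }, numeric(1))
    segmentation$positions <- pos
    segmentation$segment_correlation <- r
  }
  segmentation$colors <- grDevices::rainbow(256L, end = 0.8)[
    pmin(255L, pmax(0L, round(segmentation$positions * 255))) + 1L]
  segmentation
}

#' @export
print.segmentation <- function(x, ...) {
  k <- length(x$segments)
  cat(sprintf("Segmentation: %d segment(s) over %d pixels\n", k, length(x$labels)))
  df <- data.frame(segment = seq_len(k), size = lengths(x$segments),
                   cohesion = round(x$cohesion, 3))
  if (!is.null(x$positions)) df$position <- round(x$positions, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot a segmentation as a label map
#'
#' @param x a colored `segmentation`.
#' @param coords n x 2 pixel coordinates (um) matching the segmented spectra.
#' @param ... passed to [graphics::plot()].
#' @export
plot.segmentation <- function(x, coords, ...) {
  if (is.null(x$colors)) x <- color_segments(x)
  graphics::plot(coords[, 1], -coords[, 2], col = x$colors[x$labels],
                 pch = 15, asp = 1, xlab = "x (um)", ylab = "-y (um)", ...)
  invisible(x)
}
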