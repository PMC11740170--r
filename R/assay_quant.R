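#' Quantify assay spots on a scanned image
#'
#' For each spot, the raw optical density is the mean intensity inside the
#' spot disk minus the median intensity of a local background annulus
#' (1.1 to 1.5 spot radii), floored at zero. The annulus median makes the
#' background estimate robust to scanner gradients.
#'
#' @param image an `assay_image` (matrix with `scale` um/px and `origin`
#'   attributes registering it to the layout frame).
#' @param layout an `array_layout`.
#' @return Named numeric vector of per-spot raw OD.
#' @export
quantify_spots <- function(image, layout) {
  validate_layout(layout)
  scale <- attr(image, "scale")
  origin <- attr(image, "origin")
  if (is.null(scale) || is.null(origin))
    stopf("assay image lacks 'scale'/'origin' registration attributes")
  m <- unclass(image)
  px <- origin["x"] + (seq_len(ncol(m)) - 1) * scale
  py <- origin["y"] + (seq_len(nrow(m)) - 1) * scale
  od <- stats::setNames(numeric(nrow(layout)), layout$id)
  for (i in seq_len(nrow(layout))) {
    r <- layout$diameter[i] / 2
    if (layout$x[i] - 1.5 * r < min(px) || layout$x[i] + 1.5 * r > max(px) ||
        layout$y[i] - 1.5 * r < min(py) || layout$y[i] + 1.5 * r > max(py))
      stopf("spot %s (with its background annulus) falls outside the image",
            layout$id[i])
    cols <- which(abs(px - layout$x[i]) <= 1.5 * r)
    rows <- which(abs(py - layout$y[i]) <= 1.5 * r)
    d2 <- outer(py[rows], px[cols],
                function(y, x) dist2(x, y, layout$x[i], layout$y[i]))
    vals <- m[rows, cols, drop = FALSE]
    disk <- d2 <= r^2
    annulus <- d2 >= (1.1 * r)^2 & d2 <= (1.5 * r)^2
    if (!any(disk)) stopf("spot %s covers no image pixel", layout$id[i])
    bg <- if (any(annulus)) stats::median(vals[annulus]) else 0
    od[i] <- max(mean(vals[disk]) - bg, 0)
  }
  od
}

#' Fit the protein standard curve
#'
#' Ordinary least-squares line `OD = intercept + slope * amount` through the
#' standard spots of known amount (>= 3 standards spanning a positive
#' range).
#'
#' @param standard_ods per-standard optical densities.
#' @param known_amounts matching known amounts (ng).
#' @return A `standard_curve`: `slope` (OD/ng), `intercept` (OD), `r_squared`.
#' @export
fit_standard_curve <- function(standard_ods, known_amounts) {
  if (length(standard_ods) != length(known_amounts))
    stopf("OD and amount vectors differ in length")
  if (length(known_amounts) < 3L) stopf("need at least 3 standards")
  if (diff(range(known_amounts)) <= 0) stopf("standard amounts span no range")
  fit <- stats::lm(standard_ods ~ known_amounts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((standard_ods - mean(standard_ods))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n = length(known_amounts)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: OD = %.4g + %.4g * ng (R^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Protein amount of a spot from its Bradford OD
#'
#' Inverts the standard curve: `ng = (OD - intercept) / slope`. ODs below
#' the intercept give a negative estimate, which is floored at zero with a
#' warning.
#'
#' @param od raw OD value(s).
#' @param curve a `standard_curve`.
#' @return Estimated protein amount(s) in ng.
#' @export
protein_per_spot <- function(od, curve) {
  if (!is.finite(curve$slope) || curve$slope == 0)
    stopf("standard curve slope is zero")
  ng <- (od - curve$intercept) / curve$slope
  if (any(ng < 0)) {
    warnf("%d OD value(s) below the curve intercept; protein floored at 0",
          sum(ng < 0))
    ng <- pmax(ng, 0)
  }
  ng
}

#' Protein-normalized activity
#'
#' Activity is expressed as OD per ng of immobilized protein:
#' `raw_od / protein`. Spots with non-positive protein cannot be normalized;
#' they return `NA` and should be excluded from group statistics.
#'
#' @param raw_od raw assay OD value(s).
#' @param protein estimated protein (ng).
#' @return Normalized activity (OD/ng), `NA` where `protein <= 0`.
#' @export
normalize_activity <- function(raw_od, protein) {
  bad <- !is.finite(protein) | protein <= 0
  if (any(bad))
    warnf("%d record(s) with non-positive protein flagged (activity NA)",
          sum(bad))
  out <- raw_od / protein
  out[bad] <- NA_real_
  out
}

#' Deviation-factor outlier bounds
#'
#' Flags values outside `Y1 = mean - DF * SD` and `Y2 = mean + DF * SD`,
#' with the sample standard deviation (n - 1 denominator) and a deviation
#' factor of 1.25 by default. Flagging is strict: values equal to a bound
#' are kept.
#'
#' @param values numeric vector, length >= 3.
#' @param df deviation factor.
#' @return A `deviation_bounds`: `mean`, `sd`, `df`, `y1`, `y2`, logical
#'   `flagged`, and the surviving `kept` values.
#' @examples
#' deviation_outliers(c(1, 2, 3, 4, 100))  # flags 100
#' @export
deviation_outliers <- function(values, df = 1.25) {
  if (length(values) < 3L) stopf("need at least 3 values")
  xbar <- mean(values)
  s <- stats::sd(values)
  y1 <- xbar - df * s
  y2 <- xbar + df * s
  flagged <- values < y1 | values > y2
  structure(list(mean = xbar, sd = s, df = df, y1 = y1, y2 = y2,
                 flagged = flagged, kept = values[!flagged]),
            class = "deviation_bounds")
}

#' @export
print.deviation_bounds <- function(x, ...) {
  cat(sprintf("Deviation-factor bounds (DF = %g): mean %.4g, SD %.4g, [Y1, Y2] = [%.4g, %.4g]; %d flagged\n",
              x$df, x$mean, x$sd, x$y1, x$y2, sum(x$flagged)))
  invisible(x)
}

#' Difference-derived activity
#'
#' Several activities are only measurable as differences of two channels
#' (acetylcholinesterase = total cholinesterase - butyrylcholinesterase;
#' sigma-1 binding = total sigma - sigma-2). Records are matched spot by
#' spot and the difference of normalized activities is computed per matched
#' pair — not on group means — before any averaging; negative differences
#' are floored at zero with a warning (the activities are non-negative).
#'
#' @param minuend,subtrahend data frames of activity records with an `id`
#'   column (`by`) and an `activity` column.
#' @param by name of the matching key column (default `"spot_id"`).
#' @return A data frame of matched records with the derived `activity`;
#'   unmatched records are excluded and listed in `attr(, "unmatched")`.
#' @export
derived_activity <- function(minuend, subtrahend, by = "spot_id") {
  if (!by %in% names(minuend) || !by %in% names(subtrahend))
    stopf("both record sets need a '%s' column", by)
  keys <- intersect(minuend[[by]], subtrahend[[by]])
  unmatched <- c(setdiff(minuend[[by]], keys), setdiff(subtrahend[[by]], keys))
  if (length(unmatched))
    warnf("%d unmatched record(s) excluded: %s", length(unmatched),
          paste(unmatched, collapse = ", "))
  a <- minuend[match(keys, minuend[[by]]), , drop = FALSE]
  b <- subtrahend[match(keys, subtrahend[[by]]), , drop = FALSE]
  diff <- a$activity - b$activity
  if (any(diff < 0, na.rm = TRUE)) {
    warnf("%d negative derived activit(ies) floored at 0", sum(diff < 0, na.rm = TRUE))
    diff <- pmax(diff, 0)
  }
  out <- a
  out$activity <- diff
  attr(out, "unmatched") <- unmatched
  out
}

#' Compare activity between conditions
#'
#' One-way or two-way two-tailed ANOVA on protein-normalized activities,
#' with Tukey's post-hoc pairwise comparisons at alpha = 0.05, plus the
#' mean +/- SD per group (the conventional reporting format). Records with
#' `NA` activity (e.g. failed normalization) are dropped first.
#'
#' @param records data frame with an `activity` column and the factor
#'   column(s) named by `factors`.
#' @param design `"one-way"` (one factor) or `"two-way"` (two factors plus
#'   interaction).
#' @param factors character vector of grouping column names (1 or 2).
#' @param alpha significance level.
#' @return A `group_comparison`: the ANOVA table, Tukey results, and the
#'   per-group summary.
#' @export
group_compare <- function(records, design = c("one-way", "two-way"),
                          factors = "condition", alpha = 0.05) {
  design <- match.arg(design)
  need <- if (design == "one-way") 1L else 2L
  if (length(factors) != need)
    stopf("%s design needs %d factor column(s)", design, need)
  if (!all(c("activity", factors) %in% names(records)))
    stopf("records need 'activity' and %s column(s)",
          paste(sprintf("'%s'", factors), collapse = ", "))
  records <- records[is.finite(records$activity), , drop = FALSE]
  for (f in factors) records[[f]] <- factor(records[[f]])

  cell <- interaction(records[factors], drop = TRUE)
  sizes <- table(cell)
  if (length(sizes) < 2L) stopf("need at least 2 groups to compare")
  if (any(sizes < 3L))
    stopf("group(s) with fewer than 3 records after exclusion: %s",
          paste(names(sizes)[sizes < 3L], collapse = ", "))

  form <- if (design == "one-way")
    stats::as.formula(paste("activity ~", factors[1L]))
  else
    stats::as.formula(paste("activity ~", factors[1L], "*", factors[2L]))
  fit <- stats::aov(form, data = records)
  tukey <- stats::TukeyHSD(fit)
  summary_df <- do.call(rbind, lapply(levels(cell), function(lv) {
    v <- records$activity[cell == lv]
    data.frame(group = lv, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  structure(list(design = design, anova = summary(fit), tukey = tukey,
                 group_summary = summary_df, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s ANOVA with Tukey post-hoc (alpha = %g)\n", x$design, x$alpha))
  print(x$anova)
  cat("\nGroup means +/- SD:\n")
  print(transform(x$group_summary, mean = signif(mean, 4), sd = signif(sd, 3)),
        row.names = FALSE)
  invisible(x)
}
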