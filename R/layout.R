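#' Generate a printed-array layout
#'
#' Builds the spot map of a raft membrane microarray: a regular grid with the
#' first row holding the standard-curve spots (known protein amounts), the
#' second row blanks, and every remaining row a set of replicate spots of one
#' sample (groups are cycled across rows). The default geometry is 450 um
#' spots printed at a 950 um pitch, so neighbouring spot edges are 500 um
#' apart and spot footprints never overlap.
#'
#' @param rows,cols grid dimensions (rows >= 3 so at least one sample row
#'   follows the standard and blank rows).
#' @param pitch_um centre-to-centre spot distance in micrometres; must exceed
#'   `spot_diameter_um`.
#' @param spot_diameter_um printed spot diameter in micrometres.
#' @param groups character vector of sample (group) labels cycled over the
#'   sample rows.
#' @param standards numeric vector of known standard amounts (ng) placed left
#'   to right in the first row; `length(standards) <= cols`.
#' @return An `array_layout`: a data frame with one row per spot and columns
#'   `id`, `x`, `y` (um, origin at the top-left spot centre, x right, y down),
#'   `diameter`, `role` (sample/standard/blank), `sample_label`,
#'   `replicate_group` and `amount_ng`. The pitch is kept in
#'   `attr(, "pitch_um")`.
#' @examples
#' lay <- generate_array_layout(4, 3, groups = c("astro", "neuro"))
#' table(lay$role)
#' @export
generate_array_layout <- function(rows, cols, pitch_um = 950,
                                  spot_diameter_um = 450,
                                  groups,
                                  standards = c(0, 5, 10, 20, 40, 80)) {
  if (pitch_um <= spot_diameter_um)
    stopf("spots would overlap: pitch (%g um) must exceed spot diameter (%g um)",
          pitch_um, spot_diameter_um)
  if (rows < 3L) stopf("need at least 3 rows (standards, blanks, >=1 sample row)")
  if (length(standards) > cols)
    stopf("%d standard amounts do not fit in %d columns", length(standards), cols)
  if (length(groups) < 1L) stopf("at least one group label is required")
  groups <- as.character(groups)

  spot <- function(r, c, role, label = NA_character_,
                   rep_group = NA_character_, amount = NA_real_) {
    data.frame(id = sprintf("r%02dc%02d", r, c),
               x = (c - 1) * pitch_um, y = (r - 1) * pitch_um,
               diameter = spot_diameter_um, role = role,
               sample_label = label, replicate_group = rep_group,
               amount_ng = amount, stringsAsFactors = FALSE)
  }

  out <- list()
  for (c in seq_len(length(standards)))
    out[[length(out) + 1L]] <- spot(1L, c, "standard", amount = standards[c])
  for (c in seq_len(cols))
    out[[length(out) + 1L]] <- spot(2L, c, "blank")
  for (r in 3:rows) {
    g <- groups[((r - 3L) %% length(groups)) + 1L]
    rg <- sprintf("%s_row%02d", g, r)
    for (c in seq_len(cols))
      out[[length(out) + 1L]] <- spot(r, c, "sample", label = g, rep_group = rg)
  }
  lay <- do.call(rbind, out)
  rownames(lay) <- NULL
  attr(lay, "pitch_um") <- pitch_um
  class(lay) <- c("array_layout", "data.frame")
  lay
}

validate_layout <- function(lay) {
  problems <- character()
  need <- c("id", "x", "y", "diameter", "role", "sample_label",
            "replicate_group", "amount_ng")
  missing_cols <- setdiff(need, names(lay))
  if (length(missing_cols))
    problems <- c(problems, paste("missing field(s):",
                                  paste(missing_cols, collapse = ", ")))
  if (!length(problems)) {
    dup <- unique(lay$id[duplicated(lay$id)])
    if (length(dup))
      problems <- c(problems, paste("duplicate spot id(s):",
                                    paste(dup, collapse = ", ")))
    bad_role <- setdiff(unique(lay$role), c("sample", "standard", "blank"))
    if (length(bad_role))
      problems <- c(problems, paste("unknown role(s):",
                                    paste(bad_role, collapse = ", ")))
    std <- lay$role == "standard"
    if (any(std & !is.finite(lay$amount_ng)))
      problems <- c(problems, "standard spot(s) without known_amount_ng")
    smp <- lay$role == "sample"
    if (any(smp & (is.na(lay$replicate_group) | lay$replicate_group == "")))
      problems <- c(problems, "sample spot(s) without replicate_group")
    if (any(!is.finite(lay$diameter)) || any(lay$diameter <= 0))
      problems <- c(problems, "non-positive spot diameter")
  }
  if (length(problems))
    stopf("invalid array layout:\n  - %s", paste(problems, collapse = "\n  - "))
  invisible(lay)
}

#' Read / write an array layout as YAML
#'
#' The YAML schema has top-level `pitch_um` and a `spots` list whose entries
#' carry `id`, `x`, `y`, `diameter`, `role` and the role-dependent fields
#' (`sample_label`/`replicate_group` for samples, `amount_ng` for standards).
#' Validation reports all schema violations field by field.
#'
#' @param path file path.
#' @return `read_layout` returns an `array_layout`; `write_layout` its path,
#'   invisibly.
#' @export
read_layout <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$spots) || !length(doc$spots))
    stopf("layout file %s contains no spots", path)
  grab <- function(s, field, default = NA) {
    v <- s[[field]]
    if (is.null(v)) default else v
  }
  lay <- do.call(rbind, lapply(doc$spots, function(s) {
    data.frame(id = as.character(grab(s, "id")),
               x = as.numeric(grab(s, "x")),
               y = as.numeric(grab(s, "y")),
               diameter = as.numeric(grab(s, "diameter")),
               role = as.character(grab(s, "role")),
               sample_label = as.character(grab(s, "sample_label", NA_character_)),
               replicate_group = as.character(grab(s, "replicate_group", NA_character_)),
               amount_ng = as.numeric(grab(s, "amount_ng", NA_real_)),
               stringsAsFactors = FALSE)
  }))
  attr(lay, "pitch_um") <- if (!is.null(doc$pitch_um)) as.numeric(doc$pitch_um) else NA_real_
  class(lay) <- c("array_layout", "data.frame")
  validate_layout(lay)
  lay
}

#' @rdname read_layout
#' @param layout an `array_layout`.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  spots <- lapply(seq_len(nrow(layout)), function(i) {
    s <- as.list(layout[i, , drop = FALSE])
    s <- lapply(s, function(v) if (is.na(v)) NULL else v)
    s[!vapply(s, is.null, logical(1))]
  })
  yaml::write_yaml(list(pitch_um = attr(layout, "pitch_um"), spots = spots), path)
  invisible(path)
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("Array layout: %d spots (%d sample, %d standard, %d blank), pitch %g um\n",
              nrow(x), sum(x$role == "sample"), sum(x$role == "standard"),
              sum(x$role == "blank"), attr(x, "pitch_um")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...", nrow(x) - 8, "more spots\n")
  invisible(x)
}
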