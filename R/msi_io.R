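#' Write an MSI dataset as imzML
#'
#' Emits an imzML/ibd pair. Shared-axis datasets are written in continuous
#' mode (the m/z array stored once, referenced by every spectrum);
#' per-pixel-axis datasets in processed mode. Both arrays are 64-bit floats
#' without compression, so a write/read round trip is bit-identical.
#' Pixel positions are stored as 1-based grid indices together with the
#' raster pitch (as the scan-settings pixel size) and the micrometre origin,
#' so physical coordinates are restored exactly on read.
#'
#' @param dataset a non-empty `msi_dataset`.
#' @param path output path ending in `.imzML`; the binary `.ibd` is written
#'   alongside.
#' @return The imzML path, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  n <- n_pixels(dataset)
  if (n == 0L) stopf("no spectra: dataset is empty")
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  continuous <- is_continuous(dataset)

  mz_list <- if (continuous) rep(list(dataset$mz), n) else dataset$mz
  int_list <- if (continuous)
    lapply(seq_len(n), function(i) dataset$spectra[i, ]) else dataset$spectra

  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16L
  put <- function(x) {
    writeBin(as.double(x), con, size = 8L, endian = "little")
    off <- offset
    offset <<- offset + 8L * length(x)
    off
  }
  mz_off <- integer(n); int_off <- integer(n)
  if (continuous) {
    shared_off <- put(dataset$mz)
    mz_off[] <- shared_off
    for (i in seq_len(n)) int_off[i] <- put(int_list[[i]])
  } else {
    for (i in seq_len(n)) {
      mz_off[i] <- put(mz_list[[i]])
      int_off[i] <- put(int_list[[i]])
    }
  }

  ix <- as.integer(round((dataset$coords[, 1] - min(dataset$coords[, 1])) /
                           dataset$raster_pitch)) + 1L
  iy <- as.integer(round((dataset$coords[, 2] - min(dataset$coords[, 2])) /
                           dataset$raster_pitch)) + 1L

  cv <- function(parent, accession, name, value = NULL, cvRef = "IMS") {
    node <- xml2::xml_add_child(parent, "cvParam", cvRef = cvRef,
                                accession = accession, name = name)
    if (!is.null(value)) xml2::xml_set_attr(node, "value", as.character(value))
    node
  }
  doc <- xml2::xml_new_root("mzML", xmlns = "http://psi.hupo.org/ms/mzml",
                            version = "1.1")
  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  if (continuous) cv(fc, "IMS:1000030", "continuous")
  else cv(fc, "IMS:1000031", "processed")
  cv(fc, "IMS:1000080", "universally unique identifier",
     paste0("{", paste(format(uuid), collapse = ""), "}"))

  rpg <- xml2::xml_add_child(doc, "referenceableParamGroupList", count = "2")
  g1 <- xml2::xml_add_child(rpg, "referenceableParamGroup", id = "mzArray")
  cv(g1, "MS:1000514", "m/z array", cvRef = "MS")
  cv(g1, "MS:1000523", "64-bit float", cvRef = "MS")
  cv(g1, "MS:1000576", "no compression", cvRef = "MS")
  cv(g1, "IMS:1000101", "external data", "true")
  g2 <- xml2::xml_add_child(rpg, "referenceableParamGroup", id = "intensityArray")
  cv(g2, "MS:1000515", "intensity array", cvRef = "MS")
  cv(g2, "MS:1000523", "64-bit float", cvRef = "MS")
  cv(g2, "MS:1000576", "no compression", cvRef = "MS")
  cv(g2, "IMS:1000101", "external data", "true")

  ssl <- xml2::xml_add_child(doc, "scanSettingsList", count = "1")
  ss <- xml2::xml_add_child(ssl, "scanSettings", id = "scan1")
  cv(ss, "IMS:1000042", "max count of pixels x", max(ix))
  cv(ss, "IMS:1000043", "max count of pixels y", max(iy))
  cv(ss, "IMS:1000046", "pixel size x", dataset$raster_pitch)
  cv(ss, "IMS:1000047", "pixel size y", dataset$raster_pitch)

  icl <- xml2::xml_add_child(doc, "instrumentConfigurationList", count = "1")
  xml2::xml_add_child(icl, "instrumentConfiguration", id = "ic1")

  run <- xml2::xml_add_child(doc, "run", id = "run1")
  xml2::xml_add_child(run, "userParam", name = "origin_x_um",
                      value = as.character(min(dataset$coords[, 1])))
  xml2::xml_add_child(run, "userParam", name = "origin_y_um",
                      value = as.character(min(dataset$coords[, 2])))
  xml2::xml_add_child(run, "userParam", name = "ion_mode", value = dataset$ion_mode)
  sl <- xml2::xml_add_child(run, "spectrumList", count = as.character(n))
  for (i in seq_len(n)) {
    sp <- xml2::xml_add_child(sl, "spectrum", id = sprintf("spectrum=%d", i),
                              index = as.character(i - 1L),
                              defaultArrayLength = as.character(length(int_list[[i]])))
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    sc <- xml2::xml_add_child(scl, "scan")
    cv(sc, "IMS:1000050", "position x", ix[i])
    cv(sc, "IMS:1000051", "position y", iy[i])
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    add_arr <- function(ref, len, off) {
      ba <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
      xml2::xml_add_child(ba, "referenceableParamGroupRef", ref = ref)
      cv(ba, "IMS:1000103", "external array length", len)
      cv(ba, "IMS:1000104", "external encoded length", 8L * len)
      cv(ba, "IMS:1000102", "external offset", off)
      xml2::xml_add_child(ba, "binary")
    }
    add_arr("mzArray", length(mz_list[[i]]), mz_off[i])
    add_arr("intensityArray", length(int_list[[i]]), int_off[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an imzML file
#'
#' Supports continuous and processed mode. Pixel grid indices are converted
#' to micrometres using the scan-settings pixel size and, when present, the
#' micrometre origin recorded by [write_imzml()]; processed-mode spectra are
#' kept on their per-pixel axes until alignment.
#'
#' @param path path to the `.imzML` file (the `.ibd` must sit alongside).
#' @return An `msi_dataset`.
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("malformed imzML XML in %s: %s",
                                            path, conditionMessage(e)))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stopf("missing ibd binary: %s", ibd_path)
  xml2::xml_ns_strip(doc)

  mode_node <- xml2::xml_find_first(doc, "//fileContent/cvParam[@accession='IMS:1000030']")
  continuous <- !inherits(mode_node, "xml_missing")

  num_cv <- function(xpath, default = NA_real_) {
    node <- xml2::xml_find_first(doc, xpath)
    if (inherits(node, "xml_missing")) default
    else as.numeric(xml2::xml_attr(node, "value"))
  }
  pitch <- num_cv("//scanSettings/cvParam[@accession='IMS:1000046']", 1)
  origin_x <- num_cv("//userParam[@name='origin_x_um']", 0)
  origin_y <- num_cv("//userParam[@name='origin_y_um']", 0)
  ion_node <- xml2::xml_find_first(doc, "//userParam[@name='ion_mode']")
  ion_mode <- if (inherits(ion_node, "xml_missing")) "negative"
  else xml2::xml_attr(ion_node, "value")

  specs <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
  if (!length(specs)) stopf("no spectra in %s", path)

  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  fetch <- function(offset, len) {
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = len, size = 8L, endian = "little")
  }
  arr_meta <- function(sp, ref) {
    ba <- xml2::xml_find_first(sp, sprintf(
      "binaryDataArrayList/binaryDataArray[referenceableParamGroupRef/@ref='%s']", ref))
    if (inherits(ba, "xml_missing")) stopf("spectrum lacks %s metadata", ref)
    g <- function(acc) as.numeric(xml2::xml_attr(
      xml2::xml_find_first(ba, sprintf("cvParam[@accession='%s']", acc)), "value"))
    c(offset = g("IMS:1000102"), length = g("IMS:1000103"))
  }
  n <- length(specs)
  coords <- matrix(NA_real_, n, 2)
  mz_list <- vector("list", n); int_list <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    pos <- function(acc) as.numeric(xml2::xml_attr(
      xml2::xml_find_first(sp, sprintf(".//scan/cvParam[@accession='%s']", acc)), "value"))
    coords[i, ] <- c((pos("IMS:1000050") - 1) * pitch + origin_x,
                     (pos("IMS:1000051") - 1) * pitch + origin_y)
    m <- arr_meta(sp, "mzArray"); a <- arr_meta(sp, "intensityArray")
    mz_list[[i]] <- fetch(m["offset"], m["length"])
    int_list[[i]] <- fetch(a["offset"], a["length"])
  }
  if (continuous) {
    msi_dataset(coords, mz_list[[1]], do.call(rbind, int_list), pitch, ion_mode)
  } else {
    msi_dataset(coords, mz_list, int_list, pitch, ion_mode)
  }
}

#' Write / read a spot feature table as CSV
#'
#' One row per spot: `spot_id`, `group` and one column per m/z feature
#' (named `mz_<value>`), holding TIC-normalized intensities.
#'
#' @param table a `feature_table` (see [spot_feature_table()]) or data frame.
#' @param path file path.
#' @return `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_feature_table(df)
}
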