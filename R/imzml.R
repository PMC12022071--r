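# Minimal imzML reader/writer (continuous and processed modes).
#
# imzML stores an XML index (.imzML) next to a raw binary file (.ibd); in
# continuous mode one shared m/z array precedes the per-pixel intensity
# arrays. Only the elements needed for round-tripping pixel grids are
# emitted: UUID, mode, scan coordinates, and external-array offsets.

.IMZML_NS <- "http://psi.hupo.org/ms/mzml"

#' Write an MSI dataset as imzML (continuous mode)
#'
#' @param msi an `msi_dataset`.
#' @param path output path without extension (writes `path.imzML` and
#'   `path.ibd`).
#' @return invisibly, the two file paths.
#' @export
write_imzml <- function(msi, path) {
  stopifnot(inherits(msi, "msi_dataset"))
  ibd_path <- paste0(path, ".ibd")
  xml_path <- paste0(path, ".imzML")
  uuid <- paste0(sprintf("%08x", sample.int(.Machine$integer.max, 1)),
                 sprintf("%08x", sample.int(.Machine$integer.max, 1)),
                 sprintf("%08x", sample.int(.Machine$integer.max, 1)),
                 sprintf("%08x", sample.int(.Machine$integer.max, 1)))
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)),
                         16L)), con)
  mz_offset <- 16
  writeBin(as.numeric(msi$mz), con, size = 8, endian = "little")
  int_offset0 <- mz_offset + 8 * length(msi$mz)
  n_pix <- nrow(msi$intensities)
  for (i in seq_len(n_pix)) {
    writeBin(as.numeric(msi$intensities[i, ]), con, size = 8,
             endian = "little")
  }

  doc <- xml2::xml_new_root("mzML", xmlns = .IMZML_NS, version = "1.1")
  flc <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(flc, "fileContent")
  .cv(fc, "IMS:1000030", "continuous")
  .cv(fc, "IMS:1000080", "universally unique identifier",
      paste0("{", uuid, "}"))
  rl <- xml2::xml_add_child(doc, "referenceableParamGroupList", count = "2")
  g1 <- xml2::xml_add_child(rl, "referenceableParamGroup", id = "mzArray")
  .cv(g1, "MS:1000514", "m/z array")
  .cv(g1, "MS:1000523", "64-bit float")
  .cv(g1, "IMS:1000101", "external data", "true")
  g2 <- xml2::xml_add_child(rl, "referenceableParamGroup", id = "intensityArray")
  .cv(g2, "MS:1000515", "intensity array")
  .cv(g2, "MS:1000523", "64-bit float")
  .cv(g2, "IMS:1000101", "external data", "true")
  ss <- xml2::xml_add_child(doc, "scanSettingsList", count = "1")
  sset <- xml2::xml_add_child(ss, "scanSettings", id = "scan1")
  .cv(sset, "IMS:1000042", "max count of pixels x", as.character(msi$nx))
  .cv(sset, "IMS:1000043", "max count of pixels y", as.character(msi$ny))
  .cv(sset, "IMS:1000046", "pixel size x", as.character(msi$pitch_um))
  .cv(sset, "IMS:1000047", "pixel size y", as.character(msi$pitch_um))
  run <- xml2::xml_add_child(doc, "run", id = "run1")
  sl <- xml2::xml_add_child(run, "spectrumList", count = as.character(n_pix))
  nbin <- length(msi$mz)
  for (i in seq_len(n_pix)) {
    sp <- xml2::xml_add_child(sl, "spectrum",
                              id = sprintf("spectrum=%d", i),
                              index = as.character(i - 1),
                              defaultArrayLength = as.character(nbin))
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    scn <- xml2::xml_add_child(scl, "scan")
    .cv(scn, "IMS:1000050", "position x", as.character(msi$coords$x[i]))
    .cv(scn, "IMS:1000051", "position y", as.character(msi$coords$y[i]))
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    b1 <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
    xml2::xml_add_child(b1, "referenceableParamGroupRef", ref = "mzArray")
    .cv(b1, "IMS:1000102", "external offset", as.character(mz_offset))
    .cv(b1, "IMS:1000103", "external array length", as.character(nbin))
    xml2::xml_add_child(b1, "binary")
    b2 <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
    xml2::xml_add_child(b2, "referenceableParamGroupRef",
                        ref = "intensityArray")
    .cv(b2, "IMS:1000102", "external offset",
        as.character(int_offset0 + (i - 1) * 8 * nbin))
    .cv(b2, "IMS:1000103", "external array length", as.character(nbin))
    xml2::xml_add_child(b2, "binary")
  }
  xml2::write_xml(doc, xml_path)
  invisible(c(xml_path, ibd_path))
}

.cv <- function(node, accession, name, value = "") {
  xml2::xml_add_child(node, "cvParam",
                      cvRef = strsplit(accession, ":")[[1]][1],
                      accession = accession, name = name, value = value)
}

#' Read an imzML dataset
#'
#' Supports the continuous dialect (shared m/z array) and the processed
#' dialect (per-spectrum m/z arrays; the first spectrum's axis is used as
#' the dataset grid and all spectra must share its length).
#'
#' @param path path to the `.imzML` file (the `.ibd` must sit alongside).
#' @return an `msi_dataset`.
#' @export
read_imzml <- function(path) {
  xml_path <- if (grepl("\\.imzML$", path, ignore.case = TRUE)) path else
    paste0(path, ".imzML")
  ibd_path <- sub("\\.imzML$", ".ibd", xml_path, ignore.case = TRUE)
  if (!file.exists(xml_path)) stop("missing imzML file: ", xml_path)
  if (!file.exists(ibd_path)) stop("missing ibd file: ", ibd_path)
  doc <- xml2::read_xml(xml_path)
  ns <- c(d = .IMZML_NS)
  getv <- function(node, acc) {
    xml2::xml_attr(xml2::xml_find_first(
      node, sprintf(".//d:cvParam[@accession='%s']", acc), ns), "value")
  }
  sset <- xml2::xml_find_first(doc, ".//d:scanSettings", ns)
  nx <- as.integer(getv(sset, "IMS:1000042"))
  ny <- as.integer(getv(sset, "IMS:1000043"))
  pitch <- as.numeric(getv(sset, "IMS:1000046"))
  spectra <- xml2::xml_find_all(doc, ".//d:spectrum", ns)
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  read_arr <- function(offset, len) {
    seek(con, offset)
    readBin(con, "numeric", n = len, size = 8, endian = "little")
  }
  mz <- NULL
  xs <- integer(length(spectra)); ys <- integer(length(spectra))
  ints <- NULL
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    xs[i] <- as.integer(getv(sp, "IMS:1000050"))
    ys[i] <- as.integer(getv(sp, "IMS:1000051"))
    bdas <- xml2::xml_find_all(sp, ".//d:binaryDataArray", ns)
    for (b in bdas) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(b, ".//d:referenceableParamGroupRef", ns), "ref")
      off <- as.numeric(getv(b, "IMS:1000102"))
      len <- as.integer(getv(b, "IMS:1000103"))
      if (ref == "mzArray") {
        if (is.null(mz)) mz <- read_arr(off, len)
      } else {
        if (is.null(ints)) ints <- matrix(0, length(spectra), len)
        ints[i, ] <- read_arr(off, len)
      }
    }
  }
  out <- msi_dataset(mz, matrix(0, nx * ny, length(mz)), nx, ny, pitch)
  idx <- (xs - 1L) * ny + ys
  out$intensities[idx, ] <- ints
  out
}
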