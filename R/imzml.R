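# imzML 1.1 I/O. The format is an mzML-derived XML index file plus an .ibd
# binary companion that starts with a 16-byte UUID followed by the encoded
# m/z and intensity arrays; each spectrum's arrays are located by the
# external offset / array length cvParams from the imagingMS ontology.

IMS_NS <- "http://www.maldi-msi.org/download/imzml/imzML_1.1.0_idx.xsd"
MZML_NS <- "http://psi.hupo.org/ms/mzml"

ibd_path_for <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

random_uuid_bytes <- function() {
  # UUID v4 from R's RNG; only used as a file-pair identity token.
  b <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  b[7] <- as.raw(bitwAnd(as.integer(b[7]), 0x0f) + 0x40)
  b[9] <- as.raw(bitwAnd(as.integer(b[9]), 0x3f) + 0x80)
  b
}

uuid_to_string <- function(bytes) {
  h <- format(bytes)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

cv <- function(accession, name, value = NULL, cvref = "MS") {
  attrs <- list(cvRef = cvref, accession = accession, name = name)
  if (!is.null(value)) attrs$value <- as.character(value)
  attrs
}

#' Write an MSI datacube to an imzML/ibd file pair
#'
#' Emits a continuous-mode imzML 1.1 document: the shared m/z axis is stored
#' once in the binary companion and every pixel's intensity vector follows,
#' both as little-endian 32-bit floats. The written pair round-trips through
#' [read_imzml()] exactly at float32 precision.
#'
#' @param cube a valid `msi_cube`.
#' @param path output path ending in `.imzML`; the `.ibd` companion is
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(cube, path) {
  validate_msi_cube(cube)
  ibd <- ibd_path_for(path)
  uuid <- random_uuid_bytes()

  n <- n_pixels(cube)
  p <- length(cube$mz)
  mz_bytes <- 4L * p
  mz_offset <- 16L            # after the UUID
  int_offsets <- mz_offset + mz_bytes + 4 * p * (seq_len(n) - 1)

  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  writeBin(as.numeric(cube$mz), con, size = 4L, endian = "little")
  for (i in seq_len(n))
    writeBin(as.numeric(cube$intensities[i, ]), con, size = 4L,
             endian = "little")
  close(con); on.exit(NULL)

  doc <- xml2::xml_new_root("mzML", xmlns = MZML_NS, version = "1.1")
  add <- function(parent, name, attrs = list()) {
    node <- xml2::xml_add_child(parent, name)
    for (a in names(attrs)) xml2::xml_set_attr(node, a, attrs[[a]])
    node
  }
  cvp <- function(parent, attrs) add(parent, "cvParam", attrs)

  cvl <- add(doc, "cvList", list(count = "3"))
  add(cvl, "cv", list(id = "MS", fullName = "Proteomics Standards Initiative Mass Spectrometry Ontology",
                      URI = "http://psidev.info/ms/mzML/psi-ms.obo"))
  add(cvl, "cv", list(id = "UO", fullName = "Unit Ontology",
                      URI = "http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"))
  add(cvl, "cv", list(id = "IMS", fullName = "Imaging MS Ontology", URI = IMS_NS))

  fd <- add(doc, "fileDescription")
  fc <- add(fd, "fileContent")
  cvp(fc, cv("MS:1000579", "MS1 spectrum"))
  cvp(fc, cv("IMS:1000030", "continuous", cvref = "IMS"))
  cvp(fc, cv("IMS:1000080", "universally unique identifier",
             paste0("{", uuid_to_string(uuid), "}"), cvref = "IMS"))

  rpgl <- add(doc, "referenceableParamGroupList", list(count = "2"))
  g1 <- add(rpgl, "referenceableParamGroup", list(id = "mzArray"))
  cvp(g1, cv("MS:1000514", "m/z array"))
  cvp(g1, cv("MS:1000521", "32-bit float"))
  cvp(g1, cv("MS:1000576", "no compression"))
  cvp(g1, cv("IMS:1000101", "external data", "true", cvref = "IMS"))
  g2 <- add(rpgl, "referenceableParamGroup", list(id = "intensityArray"))
  cvp(g2, cv("MS:1000515", "intensity array"))
  cvp(g2, cv("MS:1000521", "32-bit float"))
  cvp(g2, cv("MS:1000576", "no compression"))
  cvp(g2, cv("IMS:1000101", "external data", "true", cvref = "IMS"))

  sfl <- add(doc, "softwareList", list(count = "1"))
  sw <- add(sfl, "software", list(id = "msimargin", version = "0.1.0"))
  cvp(sw, cv("MS:1000799", "custom unreleased software tool", "msimargin"))

  ssl <- add(doc, "scanSettingsList", list(count = "1"))
  ss <- add(ssl, "scanSettings", list(id = "scan1"))
  cvp(ss, cv("IMS:1000042", "max count of pixels x", cube$width, cvref = "IMS"))
  cvp(ss, cv("IMS:1000043", "max count of pixels y", cube$height, cvref = "IMS"))
  cvp(ss, cv("IMS:1000046", "pixel size (x)", cube$raster_um, cvref = "IMS"))

  icl <- add(doc, "instrumentConfigurationList", list(count = "1"))
  add(icl, "instrumentConfiguration", list(id = "IC1"))

  dpl <- add(doc, "dataProcessingList", list(count = "1"))
  dp <- add(dpl, "dataProcessing", list(id = "export"))
  pm <- add(dp, "processingMethod", list(order = "1", softwareRef = "msimargin"))
  cvp(pm, cv("MS:1000544", "Conversion to mzML"))

  run <- add(doc, "run", list(id = "run1",
                              defaultInstrumentConfigurationRef = "IC1"))
  spl <- add(run, "spectrumList", list(count = as.character(n),
                                       defaultDataProcessingRef = "export"))
  polarity <- if (cube$mode == "positive")
    cv("MS:1000130", "positive scan") else cv("MS:1000129", "negative scan")

  for (i in seq_len(n)) {
    sp <- add(spl, "spectrum",
              list(id = sprintf("spectrum=%d", i), index = as.character(i - 1L),
                   defaultArrayLength = as.character(p)))
    cvp(sp, cv("MS:1000579", "MS1 spectrum"))
    cvp(sp, polarity)
    scl <- add(sp, "scanList", list(count = "1"))
    cvp(scl, cv("MS:1000795", "no combination"))
    sc <- add(scl, "scan")
    # imzML positions are 1-based
    cvp(sc, cv("IMS:1000050", "position x", cube$coords[i, 1] + 1L, cvref = "IMS"))
    cvp(sc, cv("IMS:1000051", "position y", cube$coords[i, 2] + 1L, cvref = "IMS"))
    bal <- add(sp, "binaryDataArrayList", list(count = "2"))

    b1 <- add(bal, "binaryDataArray", list(encodedLength = "0"))
    add(b1, "referenceableParamGroupRef", list(ref = "mzArray"))
    cvp(b1, cv("IMS:1000103", "external array length", p, cvref = "IMS"))
    cvp(b1, cv("IMS:1000104", "external encoded length", mz_bytes, cvref = "IMS"))
    cvp(b1, cv("IMS:1000102", "external offset", mz_offset, cvref = "IMS"))
    add(b1, "binary")

    b2 <- add(bal, "binaryDataArray", list(encodedLength = "0"))
    add(b2, "referenceableParamGroupRef", list(ref = "intensityArray"))
    cvp(b2, cv("IMS:1000103", "external array length", p, cvref = "IMS"))
    cvp(b2, cv("IMS:1000104", "external encoded length", 4L * p, cvref = "IMS"))
    cvp(b2, cv("IMS:1000102", "external offset",
               format(int_offsets[i], scientific = FALSE), cvref = "IMS"))
    add(b2, "binary")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

# Pull the first cvParam value with a given accession below a node.
cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

cv_present <- function(node, accession) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession)), "xml_missing")
}

read_binary_slice <- function(con, offset, length, size) {
  seek(con, where = offset, origin = "start")
  readBin(con, what = "double", n = length, size = size, endian = "little")
}

#' Read an imzML/ibd file pair into an MSI datacube
#'
#' Continuous-mode files adopt the shared m/z axis as stored. Processed-mode
#' files (per-pixel peak lists) are resampled onto a common axis by
#' fixed-width binning through [bin_spectra()].
#'
#' @param path path to the `.imzML` file; the `.ibd` companion must sit
#'   alongside.
#' @param mode ionization mode override; when `NULL` the polarity cvParams
#'   of the first spectrum decide, defaulting to `"positive"` if absent.
#' @param bin_width bin width in Da used to resample processed-mode data.
#' @param raster_um pixel pitch fallback when the file carries none.
#' @return an `msi_cube`.
#' @export
read_imzml <- function(path, mode = NULL, bin_width = 0.1, raster_um = 30) {
  ibd <- ibd_path_for(path)
  if (!file.exists(path)) stop("imzML file not found: ", path)
  if (!file.exists(ibd))
    stop("missing ibd companion for ", path, " (expected ", ibd, ")")

  doc <- xml2::read_xml(path)
  continuous <- cv_present(doc, "IMS:1000030")

  # data-type encoding per referenceable param group (fall back to float32)
  enc_size <- function(group_node) {
    if (cv_present(group_node, "MS:1000523")) 8L
    else if (cv_present(group_node, "MS:1000521")) 4L
    else 4L
  }
  groups <- xml2::xml_find_all(doc, ".//d1:referenceableParamGroup")
  group_size <- vapply(groups, enc_size, integer(1))
  names(group_size) <- xml2::xml_attr(groups, "id")

  spectra <- xml2::xml_find_all(doc, ".//d1:spectrum")
  if (length(spectra) == 0L) stop("imzML file contains no spectra")

  if (is.null(mode)) {
    first <- spectra[[1]]
    mode <- if (cv_present(first, "MS:1000129")) "negative" else "positive"
  }

  px_um <- cv_value(doc, "IMS:1000046")
  if (!is.na(px_um)) raster_um <- as.numeric(px_um)

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)

  n <- length(spectra)
  xs <- integer(n); ys <- integer(n)
  peaklists <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    xs[i] <- as.integer(cv_value(sp, "IMS:1000050")) - 1L
    ys[i] <- as.integer(cv_value(sp, "IMS:1000051")) - 1L
    arrays <- xml2::xml_find_all(sp, ".//d1:binaryDataArray")
    mzv <- NULL; inv <- NULL
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, ".//d1:referenceableParamGroupRef"), "ref")
      size <- if (!is.na(ref) && ref %in% names(group_size))
        group_size[[ref]] else enc_size(arr)
      is_mz <- (!is.na(ref) && grepl("mz", ref, ignore.case = TRUE)) ||
        cv_present(arr, "MS:1000514")
      off <- as.numeric(cv_value(arr, "IMS:1000102"))
      len <- as.integer(cv_value(arr, "IMS:1000103"))
      vals <- read_binary_slice(con, off, len, size)
      if (is_mz) mzv <- vals else inv <- vals
    }
    if (is.null(mzv) || is.null(inv))
      stop("spectrum ", i, " lacks an m/z or intensity array")
    if (length(mzv) > 1 && any(diff(mzv) <= 0))
      stop("non-monotone m/z array in spectrum ", i,
           " (pixel x=", xs[i], ", y=", ys[i], ")")
    peaklists[[i]] <- cbind(mz = mzv, intensity = inv)
  }

  width <- as.integer(cv_value(doc, "IMS:1000042"))
  height <- as.integer(cv_value(doc, "IMS:1000043"))
  if (is.na(width)) width <- max(xs) + 1L
  if (is.na(height)) height <- max(ys) + 1L
  coords <- cbind(xs, ys)

  if (continuous) {
    mz <- peaklists[[1]][, "mz"]
    intens <- t(vapply(peaklists, function(pl) pl[, "intensity"],
                       numeric(length(mz))))
    cube <- msi_cube(coords, mz, intens, width, height, mode = mode,
                     raster_um = raster_um,
                     provenance = sprintf("read_imzml(%s): continuous, %d pixels",
                                          basename(path), n))
  } else {
    rng <- range(unlist(lapply(peaklists, function(pl) pl[, "mz"])))
    win <- mass_window(floor(rng[1]), ceiling(rng[2]), inclusive_high = TRUE)
    cube <- bin_spectra(peaklists, coords = coords, width = width,
                        height = height, bin_width = bin_width, range = win,
                        mode = mode, raster_um = raster_um)
    cube <- add_provenance(cube,
      sprintf("read_imzml(%s): processed mode resampled at %.3g Da",
              basename(path), bin_width))
  }
  cube
}
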