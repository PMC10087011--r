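#' Read an imzML file into an MSICube
#'
#' Parses an imzML document plus its binary \file{.ibd} companion and lays the
#' spectra out on the dense pixel grid spanned by the coordinate bounding box.
#' Both continuous and processed binary modes are supported; in processed mode
#' a common m/z axis is formed as the sorted union of all per-spectrum
#' centroids, with absent centroids stored as zero intensity (downstream peak
#' alignment/binning is the job of [peakPipeline()]).
#'
#' Grid cells inside the bounding box that carry no spectrum are marked
#' background with all-zero intensities: real DESI rasters have dropouts and
#' these are not an error. imzML 1-based x/y positions are mapped to
#' (col, row) of the internal 1-based, row-major grid.
#'
#' @param path path to the \file{.imzML} file; the \file{.ibd} companion must
#'   sit next to it (same stem).
#' @param pixel_size_um physical pixel size; if \code{NULL}, taken from the
#'   scan-settings pixel-size cvParams when present, else 1.
#' @return an \linkS4class{MSICube}
#' @examples
#' cube <- generatePhantom(seed = 1, grid_shape = c(12, 12))$msi
#' f <- file.path(tempdir(), "ex.imzML")
#' writeImzML(cube, f)
#' cube2 <- readImzML(f)
#' @export
readImzML <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("imzML file not found: ", path, call. = FALSE)
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd, path)) ibd <- paste0(path, ".ibd")
  if (!file.exists(ibd))
    stop("missing or unreadable binary companion (.ibd) for ", path,
         call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  if (is.null(pixel_size_um)) {
    px <- xml2::xml_find_first(
      doc, "//scanSettings//cvParam[@accession='IMS:1000046']")
    pixel_size_um <- if (inherits(px, "xml_missing")) 1
      else sqrt(as.numeric(xml2::xml_attr(px, "value")))
  }

  # encoding per binary array type, from the referenceable param groups
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  enc <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "cvParam"), "accession")
    bytes <- if ("MS:1000521" %in% acc) 4L else 8L
    kind <- if ("MS:1000514" %in% acc) "mz"
      else if ("MS:1000515" %in% acc) "intensity" else NA_character_
    enc[[id]] <- list(bytes = bytes, kind = kind)
  }

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  if (!length(spectra)) stop("no spectra found in ", path, call. = FALSE)

  getParam <- function(node, accession, xpath) {
    v <- xml2::xml_find_first(node, sprintf(
      ".//cvParam[@accession='%s']", accession))
    if (inherits(v, "xml_missing")) NA else xml2::xml_attr(v, "value")
  }

  con <- file(ibd, "rb")
  on.exit(close(con))
  n <- length(spectra)
  xs <- ys <- integer(n)
  mzl <- intl <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    xs[i] <- as.integer(getParam(sp, "IMS:1000050"))
    ys[i] <- as.integer(getParam(sp, "IMS:1000051"))
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    for (arr in arrays) {
      ref <- xml2::xml_attr(xml2::xml_find_first(arr,
        ".//referenceableParamGroupRef"), "ref")
      info <- enc[[ref]]
      if (is.null(info)) next
      off <- as.numeric(getParam(arr, "IMS:1000102"))
      len <- as.integer(getParam(arr, "IMS:1000103"))
      seek(con, where = off, origin = "start")
      vals <- readBin(con, "double", n = len, size = info$bytes,
                      endian = "little")
      if (identical(info$kind, "mz")) mzl[[i]] <- vals else intl[[i]] <- vals
    }
    if (is.null(mzl[[i]]) || is.null(intl[[i]]))
      stop("spectrum ", i, " lacks m/z or intensity data; corrupt file?",
           call. = FALSE)
  }

  key <- paste(xs, ys)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate pixel coordinate (x y) = ", d, " in ", path,
         call. = FALSE)
  }

  rows <- ys - min(ys) + 1L
  cols <- xs - min(xs) + 1L
  grid_shape <- c(max(rows), max(cols))

  mz_axis <- sort(unique(unlist(mzl)))
  nmz <- length(mz_axis)
  intensities <- matrix(0, nrow = nmz, ncol = prod(grid_shape))
  fg <- rep(FALSE, prod(grid_shape))
  for (i in seq_len(n)) {
    p <- linearIndex(rows[i], cols[i], grid_shape)
    idx <- match(mzl[[i]], mz_axis)
    v <- numeric(nmz)
    v[idx] <- intl[[i]]
    intensities[, p] <- v
    fg[p] <- TRUE
  }
  MSICube(intensities, mz = mz_axis, grid_shape = grid_shape,
          pixel_size_um = pixel_size_um, foreground = fg,
          meta = list(source = basename(path)))
}

#' Write an MSICube to imzML (continuous mode)
#'
#' Emits a continuous-mode imzML/ibd pair with 64-bit float m/z and intensity
#' arrays. By default only foreground pixels are written (background cells are
#' recovered as zero-intensity background on read).
#'
#' @param cube an \linkS4class{MSICube}
#' @param path output path for the \file{.imzML} file; the \file{.ibd} is
#'   written next to it.
#' @param include_background also write background pixels' (all-zero) spectra.
#' @return invisibly, the imzML path
#' @export
writeImzML <- function(cube, path, include_background = FALSE) {
  stopifnot(is(cube, "MSICube"))
  validObject(cube)
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd, path)) ibd <- paste0(path, ".ibd")

  gs <- gridShape(cube)
  cd <- colData(cube)
  keep <- if (include_background) seq_len(ncol(cube)) else
    which(cd$foreground)
  mz <- mzAxis(cube)
  nmz <- length(mz)
  uuid <- paste(sprintf("%02x", as.integer(c(
    (seq_len(16) * 37 + nmz) %% 256))), collapse = "")

  con <- file(ibd, "wb")
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)),
                         16L)), con)
  mz_offset <- 16
  writeBin(as.numeric(mz), con, size = 8, endian = "little")
  int_offsets <- numeric(length(keep))
  off <- mz_offset + 8 * nmz
  vals <- assay(cube)
  for (j in seq_along(keep)) {
    int_offsets[j] <- off
    writeBin(as.numeric(vals[, keep[j]]), con, size = 8, endian = "little")
    off <- off + 8 * nmz
  }
  close(con)

  spec_xml <- vapply(seq_along(keep), function(j) {
    p <- keep[j]
    paste0(
      sprintf('      <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n',
              j, j - 1L, nmz),
      '        <scanList count="1">\n          <scan>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', cd$col[p]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', cd$row[p]),
      '          </scan>\n        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', mz_offset),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', nmz),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n', 8 * nmz),
      '            <binary/>\n          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', int_offsets[j]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', nmz),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n', 8 * nmz),
      '            <binary/>\n          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n      </spectrum>\n')
  }, character(1))

  header <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '  <fileDescription>\n    <fileContent>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>\n',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n', uuid),
    '    </fileContent>\n  </fileDescription>\n',
    '  <referenceableParamGroupList count="2">\n',
    '    <referenceableParamGroup id="mzArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="intensityArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '  </referenceableParamGroupList>\n',
    '  <scanSettingsList count="1">\n    <scanSettings id="scan1">\n',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n', gs[2]),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n', gs[1]),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size" value="%.8g"/>\n', pixelSize(cube)^2),
    '    </scanSettings>\n  </scanSettingsList>\n',
    '  <run id="run1">\n',
    sprintf('    <spectrumList count="%d">\n', length(keep)))
  footer <- '    </spectrumList>\n  </run>\n</mzML>\n'
  writeLines(c(header, paste(spec_xml, collapse = ""), footer), path,
             sep = "")
  invisible(path)
}
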