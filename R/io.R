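# File formats: the documented columnar centroid text dialect (read/write),
# a minimal read-only mzML parser, and CSV feature tables with a
# sample-metadata sidecar.

#' Write a centroided run in the columnar text dialect
#'
#' Plain-text format: '#'-prefixed header lines carrying the sample
#' metadata, then a CSV body with columns scan, rt, mz (printed to 6
#' decimals), intensity. The format round-trips losslessly at that
#' precision.
#'
#' @param run a \linkS4class{SpectrumRun}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeRun <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# metaboScreen centroid run v1",
    paste0("# sample_id: ", run@sampleId),
    paste0("# group: ", run@group),
    paste0("# sample_type: ", run@sampleType),
    paste0("# injection_index: ", run@injectionIndex),
    paste0("# polarity: ", run@polarity),
    "scan,rt,mz,intensity"), con)
  cc <- centroids(run)
  if (nrow(cc))
    writeLines(sprintf("%d,%.4f,%.6f,%.4f", cc$scan, cc$rt, cc$mz,
                       cc$intensity), con)
  invisible(path)
}

.readRunText <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty run file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(sample_id = "sample", group = "Blank",
               sample_type = "incubation", injection_index = 1L,
               polarity = "pos")
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.*)$", h))[[1]]
    if (length(kv) == 3L && kv[2] %in% names(meta)) meta[[kv[2]]] <- kv[3]
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 1L || body[1] != "scan,rt,mz,intensity")
    stop("malformed run file (missing column header): ", path)
  if (length(body) < 2L)
    stop("run file contains no centroids: ", path)
  cc <- utils::read.csv(text = body, colClasses = c("integer", "numeric",
                                                    "numeric", "numeric"))
  SpectrumRun(cc, sampleId = meta$sample_id, group = meta$group,
              sampleType = meta$sample_type,
              injectionIndex = as.integer(meta$injection_index),
              polarity = meta$polarity)
}

# decode one <binaryDataArray> node of an mzML spectrum
.decodeBinaryArray <- function(node, ns) {
  accs <- vapply(xml2::xml_find_all(node, ".//d1:cvParam", ns),
                 function(p) xml2::xml_attr(p, "accession"), character(1))
  bytes <- if ("MS:1000521" %in% accs) 4L else 8L   # 32- vs 64-bit float
  compressed <- "MS:1000574" %in% accs              # zlib
  b64 <- xml2::xml_text(xml2::xml_find_first(node, ".//d1:binary", ns))
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if (compressed) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, "double", n = length(raw) %/% bytes, size = bytes,
          endian = "little")
}

#' Read a centroided run from an mzML file
#'
#' Minimal read-only mzML support: MS1 spectra with base64-encoded
#' (optionally zlib-compressed) 32/64-bit float arrays. Profile-mode
#' spectra are rejected with an explicit error; scan start times in minutes
#' are converted to seconds.
#'
#' @param path path to an mzML file.
#' @param sampleId,group,sampleType,injectionIndex,polarity metadata for the
#'   resulting run (mzML carries no incubation-design metadata).
#' @return a \linkS4class{SpectrumRun}.
#' @export
readMzML <- function(path, sampleId = basename(path), group = "Blank",
                     sampleType = "incubation", injectionIndex = 1L,
                     polarity = "pos") {
  doc <- xml2::read_xml(path)
  ns <- c(d1 = xml2::xml_ns(doc)[[1]])
  spectra <- xml2::xml_find_all(doc, "//d1:spectrum", ns)
  if (!length(spectra)) stop("no spectra found in ", path)
  out <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    accs <- vapply(xml2::xml_find_all(sp, "./d1:cvParam", ns),
                   function(p) xml2::xml_attr(p, "accession"), character(1))
    if ("MS:1000128" %in% accs)
      stop("profile-mode mzML spectra are not supported (spectrum ", si,
           "); centroid the data first")
    lvl <- xml2::xml_find_first(sp, "./d1:cvParam[@accession='MS:1000511']",
                                ns)
    if (!inherits(lvl, "xml_missing") &&
        xml2::xml_attr(lvl, "value") != "1") next
    rtNode <- xml2::xml_find_first(
      sp, ".//d1:cvParam[@accession='MS:1000016']", ns)
    rt <- as.numeric(xml2::xml_attr(rtNode, "value"))
    unit <- xml2::xml_attr(rtNode, "unitName")
    if (!is.na(unit) && unit == "minute") rt <- rt * 60
    arrays <- xml2::xml_find_all(sp, ".//d1:binaryDataArray", ns)
    mzArr <- intArr <- NULL
    for (a in arrays) {
      aAccs <- vapply(xml2::xml_find_all(a, ".//d1:cvParam", ns),
                      function(p) xml2::xml_attr(p, "accession"),
                      character(1))
      if ("MS:1000514" %in% aAccs) mzArr <- .decodeBinaryArray(a, ns)
      if ("MS:1000515" %in% aAccs) intArr <- .decodeBinaryArray(a, ns)
    }
    if (is.null(mzArr) || is.null(intArr)) next
    out[[si]] <- data.frame(scan = si, rt = rt, mz = mzArr,
                            intensity = intArr)
  }
  cc <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(cc) || !nrow(cc)) stop("no MS1 centroids found in ", path)
  SpectrumRun(cc, sampleId = sampleId, group = group,
              sampleType = sampleType, injectionIndex = injectionIndex,
              polarity = polarity)
}

#' Read a centroided run
#' @param path file path.
#' @param format "auto" (by extension), "text" (the columnar dialect) or
#'   "mzML".
#' @param ... metadata arguments passed to [readMzML()].
#' @return a \linkS4class{SpectrumRun}.
#' @export
readRun <- function(path, format = c("auto", "text", "mzML"), ...) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML"
      else "text"
  if (format == "mzML") readMzML(path, ...) else .readRunText(path)
}

#' Write a feature table as CSV with a sample-metadata sidecar
#'
#' The main CSV has feature rows (name, mz, rt) and one abundance column
#' per sample; the sidecar CSV holds sample_id, group, sample_type,
#' injection_index, polarity. m/z is written to 4 decimals in the report
#' style; full precision is retained in the object.
#'
#' @param fset a \linkS4class{FeatureSet}.
#' @param path main CSV path.
#' @param metaPath sidecar path; defaults to \code{path} with a
#'   "_samples.csv" suffix.
#' @param assayName assay to export.
#' @return invisibly, \code{path}.
#' @export
writeFeatureTable <- function(fset, path,
                              metaPath = sub("\\.csv$", "_samples.csv",
                                             path),
                              assayName = "abundance") {
  rd <- as.data.frame(rowData(fset))
  ab <- abundances(fset, assayName)
  out <- cbind(data.frame(name = rownames(fset),
                          mz = round(rd$mz, 4), rt = round(rd$rt, 2)),
               as.data.frame(ab))
  utils::write.csv(out, path, row.names = FALSE)
  cd <- sampleInfo(fset)
  utils::write.csv(cd, metaPath, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#' @param path main CSV path.
#' @param metaPath sidecar path.
#' @return a \linkS4class{FeatureSet}.
#' @export
readFeatureTable <- function(path,
                             metaPath = sub("\\.csv$", "_samples.csv",
                                            path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  cd <- utils::read.csv(metaPath)
  ab <- as.matrix(df[, as.character(cd$sample_id), drop = FALSE])
  rownames(ab) <- df$name
  FeatureSet(ab,
             featureData = df[, c("mz", "rt", "name")],
             sampleData = cd)
}
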