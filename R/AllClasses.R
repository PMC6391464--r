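#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData colData assay<- rowData<-
NULL

.SAMPLE_TYPES <- c("incubation", "qc", "substrate_blank", "enzyme_blank")

#' One LC-MS injection as centroided scans
#'
#' A \code{SpectrumRun} holds the centroids of a single injection (one sample
#' run through the LC-HRMS system) together with its sample metadata. The
#' centroid table has one row per mass peak with columns \code{scan}
#' (integer scan index), \code{rt} (retention time, seconds), \code{mz} and
#' \code{intensity}. Rows are ordered by scan, then m/z.
#'
#' @slot centroids data.frame of centroids (scan, rt, mz, intensity).
#' @slot sampleId character scalar, unique sample identifier.
#' @slot group incubation group label: "Blank", "Low", "High", or "QC"
#'   (blank-type runs carry "Blank").
#' @slot sampleType one of "incubation", "qc", "substrate_blank",
#'   "enzyme_blank".
#' @slot injectionIndex integer position of the run in the injection sequence
#'   (1-based), the covariate used for drift correction.
#' @slot polarity "pos" or "neg".
#'
#' @export
setClass("SpectrumRun",
  representation(
    centroids      = "data.frame",
    sampleId       = "character",
    group          = "character",
    sampleType     = "character",
    injectionIndex = "integer",
    polarity       = "character"
  ),
  prototype(
    centroids = data.frame(scan = integer(), rt = numeric(),
                           mz = numeric(), intensity = numeric()),
    sampleId = "sample", group = "Blank", sampleType = "incubation",
    injectionIndex = 1L, polarity = "pos"
  )
)

setValidity("SpectrumRun", function(object) {
  msg <- character()
  cc <- object@centroids
  need <- c("scan", "rt", "mz", "intensity")
  if (!all(need %in% names(cc)))
    msg <- c(msg, paste("centroids must have columns",
                        paste(need, collapse = ", ")))
  else {
    if (nrow(cc) && any(cc$intensity < 0))
      msg <- c(msg, "centroid intensities must be non-negative")
    if (nrow(cc) && any(cc$mz <= 0))
      msg <- c(msg, "centroid m/z values must be positive")
    if (nrow(cc) && is.unsorted(cc$scan))
      msg <- c(msg, "centroids must be ordered by scan")
  }
  if (length(object@sampleType) != 1L ||
      !object@sampleType %in% .SAMPLE_TYPES)
    msg <- c(msg, paste("sampleType must be one of",
                        paste(.SAMPLE_TYPES, collapse = ", ")))
  if (length(object@injectionIndex) != 1L || object@injectionIndex < 1L)
    msg <- c(msg, "injectionIndex must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumRun
#'
#' @param centroids data.frame with columns scan, rt, mz, intensity.
#' @param sampleId sample identifier.
#' @param group incubation group ("Blank", "Low", "High", "QC").
#' @param sampleType run type; one of "incubation", "qc", "substrate_blank",
#'   "enzyme_blank".
#' @param injectionIndex 1-based position in the injection sequence.
#' @param polarity "pos" or "neg".
#' @return A \linkS4class{SpectrumRun}.
#' @examples
#' cc <- data.frame(scan = 1:3, rt = c(0, 0.5, 1), mz = rep(218.1539, 3),
#'                  intensity = c(10, 100, 12))
#' SpectrumRun(cc, sampleId = "demo", group = "High")
#' @export
SpectrumRun <- function(centroids, sampleId = "sample", group = "Blank",
                        sampleType = "incubation", injectionIndex = 1L,
                        polarity = "pos") {
  centroids <- as.data.frame(centroids)
  ord <- order(centroids$scan, centroids$mz)
  centroids <- centroids[ord, , drop = FALSE]
  rownames(centroids) <- NULL
  new("SpectrumRun", centroids = centroids, sampleId = sampleId,
      group = group, sampleType = sampleType,
      injectionIndex = as.integer(injectionIndex), polarity = polarity)
}

#' Feature-by-sample abundance container
#'
#' \code{FeatureSet} extends \linkS4class{SummarizedExperiment}. Rows are
#' features (consensus m/z, consensus retention time, integration window and
#' name in \code{rowData}); columns are samples (group, sample type,
#' injection index and polarity in \code{colData}). The \code{"abundance"}
#' assay holds integrated peak areas (0 where a feature was neither detected
#' nor filled); the logical \code{"filled"} assay marks abundances that were
#' reintegrated from the raw data rather than detected. Processing steps add
#' further assays (\code{"log10"}, \code{"corrected"}).
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  rd <- rowData(object)
  for (col in c("mz", "rt", "name"))
    if (!col %in% names(rd))
      msg <- c(msg, sprintf("rowData column '%s' is required", col))
  cd <- colData(object)
  for (col in c("group", "sample_type", "injection_index"))
    if (!col %in% names(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("sample_type" %in% names(cd) &&
      !all(cd$sample_type %in% .SAMPLE_TYPES))
    msg <- c(msg, "unknown sample_type in colData")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureSet
#'
#' @param abundance numeric matrix, features x samples.
#' @param featureData data.frame/DataFrame with at least mz, rt, name.
#' @param sampleData data.frame/DataFrame with at least group, sample_type,
#'   injection_index.
#' @param filled optional logical matrix marking filled-in abundances;
#'   defaults to all-FALSE.
#' @return A \linkS4class{FeatureSet}.
#' @export
FeatureSet <- function(abundance, featureData, sampleData, filled = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(filled))
    filled <- matrix(FALSE, nrow(abundance), ncol(abundance))
  storage.mode(filled) <- "logical"
  featureData <- DataFrame(featureData)
  sampleData <- DataFrame(sampleData)
  if (is.null(rownames(abundance)) && "name" %in% names(featureData))
    rownames(abundance) <- make.unique(as.character(featureData$name))
  dimnames(filled) <- dimnames(abundance)
  se <- SummarizedExperiment(
    assays = list(abundance = abundance, filled = filled),
    rowData = featureData, colData = sampleData)
  new("FeatureSet", se)
}

#' @describeIn SpectrumRun-class compact display
#' @param object a SpectrumRun
#' @export
setMethod("show", "SpectrumRun", function(object) {
  cat("SpectrumRun '", object@sampleId, "' (", object@group, ", ",
      object@sampleType, ", injection ", object@injectionIndex, ", ",
      object@polarity, ")\n", sep = "")
  cc <- object@centroids
  cat("  ", nrow(cc), " centroids over ", length(unique(cc$scan)),
      " scans", sep = "")
  if (nrow(cc))
    cat(sprintf(", rt %.1f-%.1f s, m/z %.4f-%.4f",
                min(cc$rt), max(cc$rt), min(cc$mz), max(cc$mz)))
  cat("\n")
})

setMethod("show", "FeatureSet", function(object) {
  callNextMethod()
  fl <- assay(object, "filled")
  cat(sprintf("  filled cells: %d of %d (%.1f%%)\n",
              sum(fl), length(fl), 100 * mean(fl)))
})
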