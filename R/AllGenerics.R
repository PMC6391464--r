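# Generics for the accessor surface of the package's data containers.

#' Access the centroid table of a run
#' @param x a \linkS4class{SpectrumRun}
#' @return data.frame with columns scan, rt, mz, intensity
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' Sample metadata of a run or feature set
#' @param x a \linkS4class{SpectrumRun} or \linkS4class{FeatureSet}
#' @return one-row (run) or per-sample (feature set) data.frame of metadata
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Consensus feature m/z values
#' @param x a \linkS4class{FeatureSet}
#' @return numeric vector, one per feature
#' @export
setGeneric("featureMz", function(x) standardGeneric("featureMz"))

#' Consensus feature retention times (seconds)
#' @param x a \linkS4class{FeatureSet}
#' @return numeric vector, one per feature
#' @export
setGeneric("featureRt", function(x) standardGeneric("featureRt"))

#' Abundance matrix of a feature set
#' @param x a \linkS4class{FeatureSet}
#' @param which assay name, default "abundance"
#' @return numeric matrix, features x samples
#' @export
setGeneric("abundances", function(x, which = "abundance")
  standardGeneric("abundances"))

#' Logical matrix of filled-in (reintegrated) abundances
#' @param x a \linkS4class{FeatureSet}
#' @return logical matrix, features x samples
#' @export
setGeneric("isFilled", function(x) standardGeneric("isFilled"))

#' @rdname centroids
#' @export
setMethod("centroids", "SpectrumRun", function(x) x@centroids)

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "SpectrumRun", function(x) {
  data.frame(sample_id = x@sampleId, group = x@group,
             sample_type = x@sampleType,
             injection_index = x@injectionIndex,
             polarity = x@polarity)
})

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "FeatureSet", function(x)
  as.data.frame(colData(x)))

#' @rdname featureMz
#' @export
setMethod("featureMz", "FeatureSet", function(x) rowData(x)$mz)

#' @rdname featureRt
#' @export
setMethod("featureRt", "FeatureSet", function(x) rowData(x)$rt)

#' @rdname abundances
#' @export
setMethod("abundances", "FeatureSet", function(x, which = "abundance")
  assay(x, which))

#' @rdname isFilled
#' @export
setMethod("isFilled", "FeatureSet", function(x) assay(x, "filled"))
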