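# QC-anchored drift (batch) correction: per-feature linear models of log10
# abundance versus injection index, fitted on the pooled-QC injections and
# extrapolated to all samples.

#' Fit per-feature drift models on the QC injections
#'
#' A feature is eligible for correction iff it was detected (nonzero,
#' non-filled abundance) in every QC sample. For each eligible feature an
#' ordinary least-squares line of log10 abundance versus injection index is
#' fitted over the QC samples; ineligible features are flagged and later
#' passed through unchanged.
#'
#' @param fset a \linkS4class{FeatureSet} carrying a "log10" assay (see
#'   [transformAbundances()]).
#' @param assayName assay to model, default "log10".
#' @param exclude_qc character vector of QC sample ids to exclude from the
#'   fit (mirrors manual exclusion of a QC with a sensitivity loss).
#' @return data.frame with one row per feature: feature, slope, intercept,
#'   eligible, n_qc.
#' @export
fitDrift <- function(fset, assayName = "log10", exclude_qc = character()) {
  cd <- sampleInfo(fset)
  qc <- which(cd$sample_type == "qc" &
                !(rownames(cd) %in% exclude_qc) &
                !(cd$sample_id %in% exclude_qc))
  if (length(qc) < 3L)
    stop("at least 3 QC samples are required to fit drift models")
  y <- abundances(fset, assayName)[, qc, drop = FALSE]
  raw <- abundances(fset, "abundance")[, qc, drop = FALSE]
  fl <- isFilled(fset)[, qc, drop = FALSE]
  eligible <- rowSums(raw > 0 & !fl) == length(qc)
  x <- as.numeric(cd$injection_index[qc])
  xc <- x - mean(x)
  denom <- sum(xc^2)
  slope <- as.numeric(y %*% xc) / denom
  intercept <- rowMeans(y) - slope * mean(x)
  slope[!eligible] <- NA_real_
  intercept[!eligible] <- NA_real_
  data.frame(feature = rownames(fset), slope = slope,
             intercept = intercept, eligible = eligible,
             n_qc = length(qc), qc_index_mean = mean(x), row.names = NULL)
}

#' Apply drift models to a feature table
#'
#' For eligible features, \code{corrected = observed - slope * (injection
#' index - mean QC injection index)} in log10 space, for every sample
#' (extrapolating the QC trend). Centering on the mean QC injection index
#' re-anchors the corrected values so the QC mean is preserved and values
#' stay on the original scale. Ineligible features are copied unchanged.
#'
#' @param fset a \linkS4class{FeatureSet} with the modelled assay.
#' @param models data.frame from [fitDrift()].
#' @param assayName assay to correct, default "log10".
#' @return the \linkS4class{FeatureSet} with an added "corrected" assay.
#' @export
correctDrift <- function(fset, models, assayName = "log10") {
  stopifnot(identical(models$feature, rownames(fset)))
  y <- abundances(fset, assayName)
  idx <- as.numeric(sampleInfo(fset)$injection_index)
  slope <- ifelse(models$eligible, models$slope, 0)
  adj <- outer(slope, idx - models$qc_index_mean[1])
  assay(fset, "corrected", withDimnames = FALSE) <- y - adj
  fset
}

#' QC-based diagnostics of a drift correction
#'
#' Compares the per-feature coefficient of variation of the QC injections
#' before and after correction (on the linear scale, i.e. on
#' \code{10^log10}), reports the fraction of eligible features whose QC CV
#' improved, and flags outlier QC injections whose median intensity deviates
#' from the median of the QC medians by more than \code{outlier_factor}
#' (e.g. a run with a large sensitivity loss).
#'
#' @param before,after \linkS4class{FeatureSet}s sharing features and
#'   samples; \code{before} is read from \code{assay_before} (default
#'   "log10"), \code{after} from \code{assay_after} (default "corrected").
#' @param models data.frame from [fitDrift()] (for eligibility).
#' @param assay_before,assay_after assay names.
#' @param outlier_factor fold deviation of a QC run's median intensity that
#'   flags it as an outlier (default 3).
#' @return list with \code{per_feature} (feature, eligible, cv_before,
#'   cv_after, improved), \code{improved_fraction} (over eligible features),
#'   and \code{qc_outliers} (character vector of flagged QC sample ids).
#' @export
qcDiagnostics <- function(before, after, models,
                          assay_before = "log10",
                          assay_after = "corrected",
                          outlier_factor = 3) {
  cd <- sampleInfo(before)
  qc <- which(cd$sample_type == "qc")
  linB <- 10^abundances(before, assay_before)[, qc, drop = FALSE]
  linA <- 10^abundances(after, assay_after)[, qc, drop = FALSE]
  cv <- function(m) apply(m, 1, function(v) stats::sd(v) / mean(v))
  cvB <- cv(linB); cvA <- cv(linA)
  perFeature <- data.frame(
    feature = rownames(before), eligible = models$eligible,
    cv_before = cvB, cv_after = cvA,
    improved = cvA < cvB, row.names = NULL)
  elig <- models$eligible
  improvedFraction <- if (any(elig)) mean(perFeature$improved[elig]) else NA
  med <- apply(linB, 2, stats::median)
  ref <- stats::median(med)
  out <- colnames(linB)[med < ref / outlier_factor |
                          med > ref * outlier_factor]
  list(per_feature = perFeature, improved_fraction = improvedFraction,
       qc_outliers = out)
}
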