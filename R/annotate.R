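# Classification of significant features as isotopes, adducts, in-source
# artifacts, impurities, conformers/isomers or metabolites, using mass
# shifts, co-elution and blank-sample evidence.
#
# Precedence: isotope > adduct > artifact/impurity (blank evidence) >
# metabolite > isomer linking, so that a 13C peak can never accidentally
# match a biotransformation rule.

#' Match feature m/z values against adduct and transformation catalogues
#'
#' Each m/z is compared with (i) every adduct species applied to the parent
#' neutral mass and (ii) every transformation rule applied to the parent
#' protonated ion. The best match by absolute ppm error wins; any further
#' rule whose expected m/z lies within 1 ppm of the best match's expected
#' m/z is reported alongside and the match flagged ambiguous.
#'
#' @param mz numeric vector of feature m/z values.
#' @param parent_formula neutral elemental formula of the parent compound.
#' @param transformations catalogue data.frame
#'   (default [builtinTransformations()]).
#' @param adducts named list of \linkS4class{IonSpecies}
#'   (default [builtinAdducts()], positive species only are matched).
#' @param ppm_tol match tolerance in ppm (default 5).
#' @return data.frame with one row per input m/z: \code{type} ("adduct",
#'   "transformation" or NA), \code{rule} (rule/adduct label, multiple
#'   joined by "|"), \code{expected_mz}, \code{ppm}, \code{ambiguous},
#'   \code{artifact_rule} (TRUE if any matched rule is of artifact kind).
#' @export
matchMassShifts <- function(mz, parent_formula,
                            transformations = builtinTransformations(),
                            adducts = builtinAdducts(),
                            ppm_tol = 5) {
  parentMass <- monoisotopicMass(parent_formula)
  parentIon <- ionMz(parentMass, "[M+H]+")
  cand <- data.frame(
    type = c(rep("adduct", length(adducts)),
             rep("transformation", nrow(transformations))),
    rule = c(names(adducts), transformations$name),
    expected_mz = c(vapply(adducts, function(sp) ionMz(parentMass, sp),
                           numeric(1)),
                    parentIon + transformations$mass_delta),
    artifact_rule = c(rep(FALSE, length(adducts)),
                      transformations$kind == "artifact"),
    stringsAsFactors = FALSE)
  out <- data.frame(type = rep(NA_character_, length(mz)),
                    rule = NA_character_, expected_mz = NA_real_,
                    ppm = NA_real_, ambiguous = FALSE,
                    artifact_rule = FALSE)
  for (i in seq_along(mz)) {
    err <- ppmError(mz[i], cand$expected_mz)
    hit <- which(abs(err) <= ppm_tol)
    if (!length(hit)) next
    best <- hit[which.min(abs(err[hit]))]
    near <- hit[abs(ppmError(cand$expected_mz[hit],
                             cand$expected_mz[best])) <= 1]
    out$type[i] <- cand$type[best]
    out$rule[i] <- paste(unique(cand$rule[near]), collapse = "|")
    out$expected_mz[i] <- cand$expected_mz[best]
    out$ppm[i] <- err[best]
    out$ambiguous[i] <- length(unique(cand$rule[near])) > 1L
    out$artifact_rule[i] <- any(cand$artifact_rule[near])
  }
  out
}

#' Annotate 13C isotopologues
#'
#' Feature j is the k-th isotopologue of anchor i if its m/z matches
#' \code{mz(i) + k * 1.003355} within \code{ppm_tol}, the two co-elute
#' (retention times within \code{rt_tol}) and j's mean abundance is below
#' i's. Anchors are visited in order of decreasing mean abundance. When the
#' anchor's carbon count is supplied (via \code{parent_feature} and
#' \code{n_carbon}), the M+1/M abundance ratio must additionally lie within
#' a factor 2 of \code{nC x 0.0107}.
#'
#' @param fset a \linkS4class{FeatureSet}.
#' @param ppm_tol m/z tolerance (ppm) on the isotopologue position.
#' @param rt_tol co-elution tolerance (seconds).
#' @param max_k highest isotopologue checked (default 3).
#' @param parent_feature optional feature name whose composition is known.
#' @param n_carbon carbon count for \code{parent_feature}'s ion.
#' @return data.frame: feature, anchor, k, ppm (spacing error of the
#'   observed position against the expected isotopologue m/z).
#' @export
annotateIsotopes <- function(fset, ppm_tol = 5, rt_tol = 10, max_k = 3,
                             parent_feature = NULL, n_carbon = NULL) {
  mz <- featureMz(fset); rt <- featureRt(fset)
  meanAb <- rowMeans(abundances(fset))
  feats <- rownames(fset)
  assigned <- rep(FALSE, length(mz))
  rows <- list()
  for (i in order(meanAb, decreasing = TRUE)) {
    if (assigned[i]) next  # an isotope cannot anchor further isotopes
    for (k in seq_len(max_k)) {
      target <- mz[i] + k * c13Spacing()
      cand <- which(!assigned & seq_along(mz) != i &
                      abs(ppmError(mz, target)) <= ppm_tol &
                      abs(rt - rt[i]) <= rt_tol &
                      meanAb < meanAb[i])
      if (!length(cand)) next
      j <- cand[which.min(abs(ppmError(mz[cand], target)))]
      if (k == 1L && !is.null(parent_feature) && !is.null(n_carbon) &&
          feats[i] == parent_feature) {
        ratio <- meanAb[j] / meanAb[i]
        expect <- n_carbon * 0.0107
        if (ratio < expect / 2 || ratio > expect * 2) next
      }
      assigned[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feats[j], anchor = feats[i], k = k,
        ppm = ppmError(mz[j], target))
    }
  }
  if (!length(rows))
    return(data.frame(feature = character(), anchor = character(),
                      k = integer(), ppm = numeric()))
  do.call(rbind, rows)
}

#' Origin classification ladder for a significant feature
#'
#' Decision ladder combining mass-shift, co-elution and blank-sample
#' evidence: (1) a feature matching a non-enzymatic (artifact-kind) shift
#' that co-elutes with its precursor is an in-source artifact candidate;
#' (2) present in the enzyme blank (drug without enzymes) but absent from
#' the substrate blank (enzymes without drug): an impurity of the drug
#' powder; (3) present in the substrate blank: a background contaminant;
#' (4) absent from both blanks and dose-responsive: a metabolite. Ties
#' resolve in this order. Without blank runs the origin is "undetermined",
#' never guessed.
#'
#' @param artifact_rule_match TRUE if the feature matches an artifact-kind
#'   mass-shift rule.
#' @param coelutes_with_parent TRUE if the feature's retention time is
#'   within tolerance of its precursor's.
#' @param in_enzyme_blank,in_substrate_blank presence calls in the blank
#'   runs (NA if those runs are missing).
#' @param dose_responsive TRUE if the feature passes the significance filter
#'   with increasing abundance from Blank to High.
#' @return one of "artifact", "impurity", "background", "metabolite",
#'   "unknown", "undetermined".
#' @export
classifyOrigin <- function(artifact_rule_match, coelutes_with_parent,
                           in_enzyme_blank, in_substrate_blank,
                           dose_responsive) {
  if (isTRUE(artifact_rule_match) && isTRUE(coelutes_with_parent))
    return("artifact")
  if (is.na(in_enzyme_blank) || is.na(in_substrate_blank))
    return("undetermined")
  if (in_enzyme_blank && !in_substrate_blank) return("impurity")
  if (in_substrate_blank) return("background")
  if (dose_responsive) return("metabolite")
  "unknown"
}

#' Number isomeric features by ascending retention time
#'
#' Features carrying the same matched rule (or species) at retention times
#' further apart than \code{rt_tol} are cross-linked as isomers of each
#' other and numbered 1, 2, ... by ascending retention time.
#'
#' @param ann annotation data.frame with columns feature, rt, class, rule.
#' @param rt_tol minimum retention-time separation (seconds).
#' @return the data.frame with isomer_group and isomer_number filled in.
#' @export
annotateIsomers <- function(ann, rt_tol = 10) {
  ann$isomer_group <- NA_character_
  ann$isomer_number <- NA_integer_
  linkable <- !ann$class %in% c("isotope", "unknown", "undetermined") &
    !is.na(ann$rule)
  key <- paste(ann$class, ann$rule)
  for (k in unique(key[linkable])) {
    idx <- which(linkable & key == k)
    if (length(idx) < 2L) next
    idx <- idx[order(ann$rt[idx])]
    if (min(diff(ann$rt[idx])) <= rt_tol) next  # not resolved: no link
    ann$isomer_group[idx] <- k
    ann$isomer_number[idx] <- seq_along(idx)
  }
  ann
}

# presence call in blank-type runs: needs to rise above integrated noise AND
# be a relevant fraction of the incubation-level abundance, so that low-level
# chemical bleed never counts as "contained in the blank"
.blankPresence <- function(blankMean, noiseArea, maxGroupMean,
                           presence_factor, presence_frac) {
  blankMean > presence_factor * noiseArea &
    blankMean > presence_frac * maxGroupMean
}

#' Annotate a table of significant features
#'
#' Runs the full annotation cascade on a (typically filtered)
#' \linkS4class{FeatureSet}: parent identification, 13C isotopologues,
#' adducts, biotransformation mass shifts with origin classification
#' (artifact / impurity / background / metabolite), a second pass linking
#' artifact-kind shifts to identified impurities, conformer detection at
#' the parent m/z, and isomer numbering.
#'
#' @param fset a \linkS4class{FeatureSet} containing, if available, the
#'   enzyme-blank and substrate-blank samples (sample_type
#'   "enzyme_blank" / "substrate_blank") used for origin evidence.
#' @param parent_formula neutral formula of the incubated parent compound.
#' @param transformations,adducts catalogues (defaults as in
#'   [matchMassShifts()]).
#' @param ppm_tol mass tolerance (ppm, default 5).
#' @param rt_tol co-elution tolerance (seconds, default 10).
#' @param comparisons optional [compareGroups()] output for the
#'   dose-responsiveness call; computed from \code{fset} if absent and the
#'   incubation groups are present.
#' @param fc_thresh,p_thresh thresholds defining dose-responsiveness
#'   (positive Blank-to-High fold change with significant p).
#' @param presence_factor blank presence must exceed this multiple of the
#'   integrated-noise level (default 3).
#' @param presence_frac ... and this fraction of the feature's highest
#'   incubation group mean (default 0.1).
#' @param noise_area noise-level abundance; estimated as the median of the
#'   filled-in abundances when NULL.
#' @return annotation data.frame, one row per feature: feature, mz, rt,
#'   class, rule, identity, ppm_error, parent_feature, isotope_k,
#'   isomer_group, isomer_number, ambiguous, coelutes_with_parent,
#'   in_enzyme_blank, in_substrate_blank, dose_responsive.
#' @export
annotateFeatures <- function(fset, parent_formula,
                             transformations = builtinTransformations(),
                             adducts = builtinAdducts(),
                             ppm_tol = 5, rt_tol = 10,
                             comparisons = NULL,
                             fc_thresh = 1.5, p_thresh = 0.001,
                             presence_factor = 3, presence_frac = 0.1,
                             noise_area = NULL) {
  mz <- featureMz(fset); rt <- featureRt(fset)
  feats <- rownames(fset)
  ab <- abundances(fset)
  cd <- sampleInfo(fset)
  meanAb <- rowMeans(ab)
  n <- length(feats)

  # ---- evidence ----
  inc <- cd$sample_type == "incubation"
  groupMean <- function(g) {
    cols <- inc & cd$group == g
    if (any(cols)) rowMeans(ab[, cols, drop = FALSE]) else rep(NA_real_, n)
  }
  maxGroupMean <- pmax(groupMean("Blank"), groupMean("Low"),
                       groupMean("High"), na.rm = TRUE)
  if (is.null(noise_area)) {
    fills <- ab[isFilled(fset) & ab > 0]
    noise_area <- if (length(fills)) stats::median(fills) else
      min(ab[ab > 0])
  }
  blankMean <- function(type) {
    cols <- cd$sample_type == type
    if (any(cols)) rowMeans(ab[, cols, drop = FALSE]) else rep(NA_real_, n)
  }
  enzMean <- blankMean("enzyme_blank")
  subMean <- blankMean("substrate_blank")
  inEnz <- .blankPresence(enzMean, noise_area, maxGroupMean,
                          presence_factor, presence_frac)
  inSub <- .blankPresence(subMean, noise_area, maxGroupMean,
                          presence_factor, presence_frac)
  doseResp <- rep(FALSE, n)
  if (is.null(comparisons) &&
      all(c("Blank", "Low", "High") %in% cd$group[inc]))
    comparisons <- compareGroups(fset)
  if (!is.null(comparisons)) {
    bh <- comparisons[comparisons$comparison == "Blank-High", ]
    hit <- bh$feature[!is.na(bh$fold_change) &
                        bh$fold_change > fc_thresh & bh$p < p_thresh]
    doseResp <- feats %in% hit
  }

  ann <- data.frame(
    feature = feats, mz = mz, rt = rt, class = "unknown",
    rule = NA_character_, identity = NA_character_,
    ppm_error = NA_real_, parent_feature = NA_character_,
    isotope_k = NA_integer_, isomer_group = NA_character_,
    isomer_number = NA_integer_, ambiguous = FALSE,
    coelutes_with_parent = NA, in_enzyme_blank = inEnz,
    in_substrate_blank = inSub, dose_responsive = doseResp,
    row.names = NULL)

  # ---- parent ----
  parentMass <- monoisotopicMass(parent_formula)
  parentIonMz <- ionMz(parentMass, "[M+H]+")
  pc <- which(abs(ppmError(mz, parentIonMz)) <= ppm_tol)
  parentIdx <- NA_integer_
  if (length(pc)) {
    parentIdx <- pc[which.max(meanAb[pc])]
    ann$class[parentIdx] <- "parent"
    ann$rule[parentIdx] <- "[M+H]+"
    ann$ppm_error[parentIdx] <- ppmError(mz[parentIdx], parentIonMz)
    ann$identity[parentIdx] <- "parent"
  }
  parentRt <- if (!is.na(parentIdx)) rt[parentIdx] else NA_real_
  ann$coelutes_with_parent <- if (!is.na(parentRt))
    abs(rt - parentRt) <= rt_tol else NA
  nC <- as.integer(c(parseFormula(parent_formula)["C"]))

  # ---- isotopes ----
  iso <- annotateIsotopes(fset, ppm_tol = ppm_tol, rt_tol = rt_tol,
                          parent_feature = if (!is.na(parentIdx))
                            feats[parentIdx] else NULL,
                          n_carbon = nC)
  for (r in seq_len(nrow(iso))) {
    i <- match(iso$feature[r], feats)
    ann$class[i] <- "isotope"
    ann$isotope_k[i] <- iso$k[r]
    ann$parent_feature[i] <- iso$anchor[r]
    ann$ppm_error[i] <- iso$ppm[r]
    ann$identity[i] <- sprintf("13C%s-isotope of %s",
                               if (iso$k[r] > 1) iso$k[r] else "",
                               iso$anchor[r])
  }

  # ---- adducts and transformations ----
  open <- which(ann$class == "unknown")
  if (length(open)) {
    shiftAdducts <- adducts[names(adducts) != "[M+H]+"]
    ms <- matchMassShifts(mz[open], parent_formula,
                          transformations = transformations,
                          adducts = shiftAdducts, ppm_tol = ppm_tol)
    for (r in seq_along(open)) {
      i <- open[r]
      if (is.na(ms$type[r])) next
      ann$rule[i] <- ms$rule[r]
      ann$ppm_error[i] <- ms$ppm[r]
      ann$ambiguous[i] <- ms$ambiguous[r]
      ann$parent_feature[i] <- if (!is.na(parentIdx))
        feats[parentIdx] else NA_character_
      if (ms$type[r] == "adduct") {
        ann$class[i] <- "adduct"
        ann$identity[i] <- sprintf("adduct %s", ms$rule[r])
      } else {
        cls <- classifyOrigin(ms$artifact_rule[r],
                              isTRUE(ann$coelutes_with_parent[i]),
                              inEnz[i], inSub[i], doseResp[i])
        ann$class[i] <- cls
        ann$identity[i] <- switch(cls,
          artifact = sprintf("artifact (%s)", ms$rule[r]),
          impurity = sprintf("impurity (%s)", ms$rule[r]),
          metabolite = sprintf("M (%s)", ms$rule[r]),
          background = "background contaminant",
          sprintf("%s (%s)", cls, ms$rule[r]))
      }
    }
  }

  # ---- unmatched features: blank-evidence ladder without a rule ----
  open <- which(ann$class == "unknown")
  for (i in open) {
    if (is.na(inEnz[i]) || is.na(inSub[i])) {
      ann$class[i] <- "undetermined"
      ann$identity[i] <- "undetermined (blank runs missing)"
    } else if (inEnz[i] && !inSub[i]) {
      ann$class[i] <- "impurity"
      ann$identity[i] <- "impurity (uncatalogued shift)"
    } else if (inSub[i]) {
      ann$class[i] <- "background"
      ann$identity[i] <- "background contaminant"
    }
  }

  # ---- artifacts of impurities (second-level shifts) ----
  open <- which(ann$class == "unknown")
  imp <- which(ann$class == "impurity")
  if (length(open) && length(imp)) {
    art <- transformations[transformations$kind == "artifact", ,
                           drop = FALSE]
    for (i in open) {
      for (j in imp) {
        err <- ppmError(mz[i], mz[j] + art$mass_delta)
        hit <- which(abs(err) <= ppm_tol)
        if (length(hit) &&
            isTRUE(inEnz[i]) && !isTRUE(inSub[i])) {
          best <- hit[which.min(abs(err[hit]))]
          ann$class[i] <- "artifact"
          ann$rule[i] <- art$name[best]
          ann$ppm_error[i] <- err[best]
          ann$parent_feature[i] <- feats[j]
          ann$identity[i] <- sprintf("impurity artifact (%s)",
                                     art$name[best])
          break
        }
      }
      if (ann$class[i] != "unknown") next
    }
  }

  # ---- conformers: same m/z as the parent at another retention time ----
  conf <- which(ann$class == "unknown" &
                  abs(ppmError(mz, parentIonMz)) <= ppm_tol)
  if (!is.na(parentIdx) && length(conf)) {
    ann$class[conf] <- "conformer"
    ann$rule[conf] <- "[M+H]+"
    ann$ppm_error[conf] <- ppmError(mz[conf], parentIonMz)
    ann$parent_feature[conf] <- feats[parentIdx]
    ann$identity[conf] <- "parent conformer"
  }

  # ---- isomer numbering ----
  ann <- annotateIsomers(ann, rt_tol = rt_tol)
  lab <- !is.na(ann$isomer_number) & ann$class %in%
    c("metabolite", "conformer", "parent")
  ann$identity[lab] <- paste0(ann$identity[lab], " isomer ",
                              ann$isomer_number[lab])
  ann
}
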