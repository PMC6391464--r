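---
title: "Untargeted LC-HRMS screening for in vitro drug metabolites: methods and design"
author: "metaboScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted LC-HRMS screening for in vitro drug metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Metabolism studies of new psychoactive substances (NPS) traditionally rely
on an expert inspecting fragment spectra and deciding, compound by
compound, what is a metabolite. Untargeted metabolomics replaces that
judgement with a statistical screen: incubate the drug with pooled human
liver microsomes (pHLM) at several doses, record full-scan LC-HRMS data of
every incubation, detect chromatographic features, and let dose-response
statistics nominate the features worth identifying. `metaboScreen`
implements that workflow end to end, together with a ground-truth
simulator so that every stage is testable without access to instrument
data.

The study design the package models is: three incubation groups — Blank
(0 µM substrate), Low (12.5 µM) and High (25 µM) — with five replicates
each; a pooled QC sample (equal aliquots of all fifteen incubations)
injected five times at the start of the sequence and then after every
fifth sample; and duplicate *substrate blanks* (enzymes, no drug) and
*enzyme blanks* (drug, no enzymes) used as evidence when classifying the
origin of significant features.

# The processing model

## Peak detection and features

Centroided runs are converted to extracted-ion traces by greedy m/z-trace
building: a centroid joins an open region of interest (ROI) when it lies
within `ppm_tol` of the ROI's running mean m/z; traces shorter than
`min_scans` scans are dropped. Each trace is smoothed with a narrow
Gaussian kernel; local maxima with signal-to-noise ≥ `snr_min` (noise =
MAD of the raw-minus-smoothed residual, floored at one count) become
peaks, bounded at the flanking local minima. The bound walk additionally
stops once the smoothed signal has decayed to 1% of the apex above
baseline, so an isolated peak is bounded near its feet rather than at the
trace edges; areas are trapezoid integrals of the raw trace. Peaks are
grouped across samples by single-linkage in m/z (5 ppm) then retention
time (10 s); features are named `M<round(m/z)>T<round(rt)>` with half-up
rounding (the convention fixes the tie case; a single published example
cannot discriminate between rounding modes).

Where a sample lacks a member peak the feature's consensus retention-time
window is reintegrated from that sample's raw data (*gap filling*). In
blank-group samples this deliberately integrates noise — reproducing the
well-known phenomenon that blank groups show large within-group variance
for drug-derived features.

## Significance filter

For every feature, signed fold changes and Welch two-sample t-tests are
computed for Blank–Low, Blank–High and Low–High **on the raw abundances**
(the transformation comes later in the stated order of operations; a
configuration switch can move the tests to the log scale). The signed fold
change is the ratio of group means when ≥ 1 and the negative reciprocal
otherwise, so the keep-rule "FC < −1.5 or > 1.5" is symmetric. A feature
is significant iff some single comparison has |FC| > 1.5 **and** p < 0.001
(the FC and the p must come from the *same* comparison), and its retention
time lies in [60, 600] s inclusive (earlier/later peaks elute during
column equilibration or washing). Degenerate fold changes: both means
zero gives an undefined sentinel that never passes; one zero mean gives a
signed infinity that satisfies the FC criterion, with the p-value still
gating. No multiple-testing correction is applied — the workflow is
faithful to a raw p < 0.001 gate; users wanting FDR control can filter
`compareGroups()` output themselves.

## Zero replacement, transformation and drift correction

Zeros are replaced by the smallest strictly positive abundance of the
whole table (a surrogate limit of detection — global, not per feature),
then abundances are log10 transformed. Features detected (not filled) in
*every* QC injection are eligible for drift correction: an ordinary
least-squares line of log10 abundance versus injection index is fitted on
the QC samples only and subtracted from **all** samples, centred on the
mean QC injection index so the QC mean is preserved. A single global line
is the default reading of "a linear model extrapolating the drift between
QC samples"; segment-wise interpolation between consecutive QCs is a
plausible alternative reading, but the global line is the simpler model,
is exactly right for the linear sensitivity decay the simulator plants,
and extrapolates stably beyond the first/last QC. Ineligible features
pass through bit-identically. QC diagnostics report per-feature QC
coefficients of variation (linear scale) before/after, and flag QC
injections whose median intensity deviates more than 3-fold from the
median of QC medians (mirroring the manual exclusion of a QC run that
suffered a sensitivity loss); exclusion remains manual via
`fitDrift(exclude_qc=)`.

## Multivariate diagnostics

PCA is the eigendecomposition of the covariance of column-centred data
(no scaling — with a dominating parent compound, PC1 then absorbs > 95%
of the variance, the collinearity signature of this design). Component
signs are fixed by making the largest-magnitude loading positive, for
testability. t-SNE is an exact (non-Barnes-Hut) implementation — no R
t-SNE package is assumed — with perplexity 5 (≈ group size), 1000
iterations and a fixed seed; at a few dozen samples the exact gradient is
cheap. Hierarchical clustering z-scores each feature across samples and
clusters samples and features with Euclidean distance and complete
linkage; the distance/linkage choice is not dictated by the workflow and
is exposed as a parameter of the analysis functions.

## Annotation

Annotation proceeds in strict precedence — isotope > adduct >
artifact/impurity (blank evidence) > metabolite > isomer linking — so a
¹³C peak can never accidentally match a biotransformation rule.

* **Isotopes**: feature j is the k-th isotopologue of anchor i if
  m/z(j) ≈ m/z(i) + k × 1.003355 (5 ppm), the two co-elute (10 s), and j
  is less abundant; where the anchor's carbon count is known the M+1/M
  ratio must lie within a factor 2 of nC × 0.0107.
* **Adducts**: catalogued ion species applied to the parent neutral mass,
  including the chloride-bridged proton-bound dimer [2M+2H+Cl]⁺. Ion m/z
  uses the proton mass (1.00727646 Da) in both polarities and neglects
  the electron mass — standard small-molecule practice, accurate well
  below the 5 ppm tolerance.
* **Biotransformations**: catalogued element deltas applied to the
  protonated parent — dihydro- (+H₂), dehydro- (−H₂), HO- (+O), di-HO-
  (+O₂), oxo- (+O−H₂), dihydro-HO- (+H₂+O), dihydro-oxo- (net +O),
  oxo-HO- (+O₂−H₂), N,N-dealkyl- (−C₄H₆), plus the non-enzymatic imido-
  (+NH−O) and cyano- (+CHN, HCN addition from acetonitrile). Note the
  cyano- delta is +CHN, not +CN−H: the printed masses of the cyano
  artifacts sit exactly one HCN above their dehydro precursors. HO- and
  dihydro-oxo- share the same net +O shift and can never be separated by
  MS¹ mass alone; such matches are reported with both rules and flagged
  ambiguous.
* **Origin ladder**: (1) a feature matching a *non-enzymatic* shift
  (dehydro-, imido-, cyano-) that co-elutes with its precursor is an
  in-source artifact; (2) present in the enzyme blank but absent from the
  substrate blank → drug-powder impurity; (3) present in the substrate
  blank → background contaminant; (4) absent from both blanks and
  dose-responsive → metabolite; otherwise unknown, and *undetermined*
  when blank runs are missing. Restricting step (1) to non-enzymatic
  rules is deliberate: genuine metabolites can and do co-elute with the
  parent (reduction products often shift retention only slightly), and
  an unrestricted co-elution rule would mislabel them. "Dose-responsive"
  means passing the significance filter with a positive Blank→High fold
  change. Blank "presence" requires the blank abundance to exceed both
  3× the integrated-noise level and 10% of the feature's largest
  incubation-group mean, so low-level chemical noise in the integration
  window never counts as "contained in the blank".
* **Isomers/conformers**: features matching the same rule (or the parent
  m/z) at retention times separated by more than the co-elution tolerance
  are cross-linked and numbered by ascending retention time.

# The synthetic world

The simulator's defaults *are* the study conditions: 3 × 5 incubations,
5 + every-5th pooled-QC injections (8 QCs in total over 15 samples),
duplicate substrate and enzyme blanks, and a linear multiplicative
sensitivity drift of −0.4% per injection — linear, because that is the
model the correction assumes, which makes slope recovery a clean
parameter-recovery test. The default chemistry is a cathinone-like parent
(C₁₄H₁₉NO, protonated m/z 218.1539, 216 s) at 2×10⁷ area units —
about 200× the median background abundance, as expected when the
incubated drug dominates the mixture — with four enzymatic metabolites at
5–18% of the parent (dose response Low 1×, High 1.7×, mildly saturating,
emulating nonlinear metabolite formation), a co-eluting in-source dehydro
artifact (3%), a dehydro powder impurity at a distinct retention time
(2%, present in the enzyme blank only), a [2M+2H+Cl]⁺ dimer adduct
(0.4%), ¹³C isotopologues for every ion (M+1/M = nC × 0.0107), and 200
dose-independent background species with log-normal abundances, some
deliberately outside the 60–600 s window. Peaks are Gaussian (σ = 4 s) on
a 0.5 s scan grid over 0–700 s; centroid m/z jitter is Normal with σ = 1
ppm; intensities carry 2% multiplicative noise. Raw intensity scales are
arbitrary — the real study reports none — and only ratios matter
downstream.

Two noise components are modelled. Sparse uniform-m/z noise centroids
(20 per scan, log-normal intensity around 500 counts) exercise
false-ROI control. Separately, every substrate-derived species receives a
small dose-independent "chemical bleed" area (log-normal, median 200
area units, ~10⁻⁵ of the parent) at its own m/z and retention time in
*every* run. This stands in for the dense chemical noise of real
high-resolution full scans: uniform random centroids are so sparse inside
a ±10 ppm extraction window that blank-region reintegration would return
exactly zero, whereas real reintegration returns small, highly variable
noise areas — the documented cause of the blank group's high within-group
variance. Point-by-point emulation of that noise density is not feasible
at desk scale, so the bleed term plants its *consequence* directly.

What the simulator does **not** emulate: retention-time shifts between
runs (no alignment/warping is implemented, deliberately), non-Gaussian
peak shapes and detector saturation, profile-mode data, isotope fine
structure (³⁷Cl etc.), charge states above 1, and MS² fragmentation. A
green end-to-end test therefore establishes that the pipeline's logic is
faithful and self-consistent on data obeying its assumptions — not that
the detector would cope with badly warped or saturated real-world
chromatograms.

# Numerical choices and degenerate inputs

* Monoisotopic masses to ≥ 6 decimals; rule mass deltas are derived from
  element maps and verified to reproduce within 10⁻⁶ Da.
* Feature-name rounding is half-up (`floor(x + 0.5)`).
* Welch's t is computed from the closed-form statistic and
  Welch–Satterthwaite df; zero-variance degeneracies return t = 0, p = 1
  (equal means) or |t| = ∞, p = 0 (unequal means). The test suite checks
  equality with `stats::t.test` to 10⁻¹⁰ and the empirical type-I error
  at α = 0.001 over 100,000 null simulations.
* Grouping ties break deterministically (peaks sorted by sample and
  retention time before linkage); feature tables are invariant to sample
  processing order.
* An all-zero abundance table, a missing incubation group, fewer than 3
  QC injections, an empty scan grid, malformed width bounds and unknown
  configuration keys are all rejected with explicit errors.
* All randomness flows from a single seed; identical configurations give
  byte-identical CSV outputs.

# Known limitations

The detector is a documented simplification, not a reimplementation of
any published picker's internals; its parameters are honest configuration
knobs, not claimed optima. The drift model is a single global line per
feature. Annotation is MS¹-only: positional isomers, diastereomers and
conformers are linked by retention order but cannot be structurally
assigned without fragmentation data, which is out of scope. One printed
reference isotopologue mass (the M+2 of the chloride dimer adduct) is
inconsistent with its implied composition by ~19 ppm while its siblings
agree within 1 ppm; it is treated as a typographical error and excluded
from the mass-regression fixture.

`scripts/acceptance.R` re-runs the default synthetic study from scratch
and reports the percentage of variance captured by PC1 of the processed
feature table; the test suite computes every other claim made here.
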