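# Ground-truth simulator for centroided LC-HRMS incubation studies.
#
# The stated world: three incubation groups (Blank = 0 uM, Low = 12.5 uM,
# High = 25 uM substrate) x 5 replicates, a pooled QC injected 5x at the
# start of the sequence and then after every 5th sample, plus duplicate
# substrate-blank (enzymes, no drug) and enzyme-blank (drug, no enzymes)
# runs. Each run carries the parent compound, dose-dependent metabolites at
# catalogued mass shifts, 13C isotopologues, adducts, a co-eluting in-source
# artifact, a drug-powder impurity, dose-independent background species, and
# a linear injection-order sensitivity drift.

#' Describe one simulated chemical species
#'
#' @param name species label (used in the ground-truth ledger).
#' @param formula neutral elemental formula (string).
#' @param rt_apex chromatographic apex retention time, seconds.
#' @param rt_sigma Gaussian peak width (sd), seconds; must be > 0.
#' @param base_abundance integrated area (arbitrary intensity units) of the
#'   main ion at multiplier 1, pre-drift.
#' @param dose_response named multipliers for groups Blank/Low/High;
#'   substrate-derived species must have Blank = 0.
#' @param adducts named numeric vector: adduct label -> fraction of
#'   \code{base_abundance} carried by that ion (default single [M+H]+).
#' @param class species class for the ledger: one of "parent", "metabolite",
#'   "artifact", "impurity", "background".
#' @param origin what the species' presence depends on: "substrate" (present
#'   wherever the drug is, including the enzyme blank), "enzymatic" (needs
#'   drug plus enzymes: incubations and QC only), or "background"
#'   (everywhere).
#' @param is_artifact_of optional name of a parent species; forces
#'   \code{rt_apex} to the parent's apex (in-source artifacts co-elute).
#' @return a list of class "CompoundSpec".
#' @export
compoundSpec <- function(name, formula, rt_apex, rt_sigma = 4,
                         base_abundance,
                         dose_response = c(Blank = 0, Low = 1, High = 2),
                         adducts = c("[M+H]+" = 1),
                         class = "metabolite",
                         origin = c("enzymatic", "substrate", "background"),
                         is_artifact_of = NULL) {
  origin <- match.arg(origin)
  stopifnot(rt_sigma > 0, all(dose_response >= 0),
            all(c("Blank", "Low", "High") %in% names(dose_response)))
  if (origin != "background" && dose_response[["Blank"]] != 0)
    stop("substrate-derived species must have a Blank multiplier of 0")
  structure(list(
    name = name, formula = formula, rt_apex = rt_apex, rt_sigma = rt_sigma,
    base_abundance = base_abundance, dose_response = dose_response,
    adducts = adducts, class = class, origin = origin,
    is_artifact_of = is_artifact_of), class = "CompoundSpec")
}

# multiplier of a species in a given run
.speciesMultiplier <- function(sp, group, sampleType) {
  dr <- sp$dose_response
  switch(sampleType,
    incubation = dr[[group]],
    qc = mean(dr[c("Blank", "Low", "High")]),
    enzyme_blank = switch(sp$origin,
      substrate = dr[["High"]], enzymatic = 0, background = 1),
    substrate_blank = switch(sp$origin,
      substrate = 0, enzymatic = 0, background = 1))
}

#' Default incubation-study scenario
#'
#' A cathinone-like parent (C14H19NO, protonated m/z 218.1539, apex 216 s)
#' dominating the run at ~200x the median background abundance, with four
#' enzymatic metabolites (dihydro-, oxo-, dihydro-HO-, di-HO-) at saturating
#' dose response, a co-eluting in-source dehydro artifact, a dehydro powder
#' impurity at a distinct retention time, a chloride-bridged dimer adduct,
#' and 200 dose-independent background species. Drift is -0.4% of
#' sensitivity per injection. All values are fixed properties of the stated
#' world; see the methods vignette for the reasoning behind each default.
#'
#' @param n_background number of dose-independent background species.
#' @param seed RNG seed controlling every random draw of the study.
#' @return scenario list understood by [simulateStudy()].
#' @export
defaultScenario <- function(n_background = 200, seed = 42) {
  parentFormula <- "C14H19NO"
  parentBase <- 2e7
  met <- function(name, delta, rt, frac)
    compoundSpec(name, formulaToString(applyDelta(parentFormula, delta)),
                 rt_apex = rt, base_abundance = frac * parentBase,
                 dose_response = c(Blank = 0, Low = 1, High = 1.7),
                 class = "metabolite", origin = "enzymatic")
  species <- list(
    compoundSpec("parent", parentFormula, rt_apex = 216,
                 base_abundance = parentBase,
                 dose_response = c(Blank = 0, Low = 1, High = 2),
                 adducts = c("[M+H]+" = 1, "[2M+2H+Cl]+" = 0.004),
                 class = "parent", origin = "substrate"),
    met("M-dihydro",    "+H2",    226, 0.12),
    met("M-oxo",        "+O-H2",  343, 0.18),
    met("M-dihydro-HO", "+H2+O",  367, 0.08),
    met("M-di-HO",      "+O2",    412, 0.05),
    compoundSpec("parent-dehydro-artifact",
                 formulaToString(applyDelta(parentFormula, "-H2")),
                 rt_apex = 216, base_abundance = 0.03 * parentBase,
                 dose_response = c(Blank = 0, Low = 1, High = 2),
                 class = "artifact", origin = "substrate",
                 is_artifact_of = "parent"),
    compoundSpec("powder-impurity-dehydro",
                 formulaToString(applyDelta(parentFormula, "-H2")),
                 rt_apex = 114, base_abundance = 0.02 * parentBase,
                 dose_response = c(Blank = 0, Low = 1, High = 2),
                 class = "impurity", origin = "substrate")
  )
  list(
    parent_name = "parent",
    parent_formula = parentFormula,
    species = species,
    n_background = n_background,
    background = list(mz_range = c(100, 700), rt_range = c(20, 680),
                      meanlog = log(1e5), sdlog = 1),
    design = list(replicates = 5L, qc_lead_in = 5L, qc_every = 5L,
                  n_substrate_blank = 2L, n_enzyme_blank = 2L),
    drift_rate = -0.004,
    grid = list(rt_min = 0, rt_max = 699.5, interval = 0.5),
    noise = list(density = 20, meanlog = log(500), sdlog = 1,
                 sigma_ppm = 1, intensity_cv = 0.02,
                 bleed_area = 200, bleed_sdlog = 0.5),
    seed = seed
  )
}

#' Small scenario for fast tests
#'
#' Same structure as [defaultScenario()] but with few background species and
#' a coarser, shorter scan grid.
#' @param ... overrides passed through to the scenario list.
#' @return scenario list.
#' @export
smallScenario <- function(...) {
  sc <- defaultScenario(n_background = 10)
  sc$grid <- list(rt_min = 0, rt_max = 499, interval = 1)
  sc$background$rt_range <- c(20, 480)
  sc$noise$density <- 5
  dots <- list(...)
  sc[names(dots)] <- dots
  sc
}

# draw the background species inventory (fixed across runs of one study)
.backgroundSpecies <- function(scenario) {
  n <- scenario$n_background
  if (!n) return(list())
  bg <- scenario$background
  mz <- stats::runif(n, bg$mz_range[1], bg$mz_range[2])
  rt <- stats::runif(n, bg$rt_range[1], bg$rt_range[2])
  ab <- stats::rlnorm(n, bg$meanlog, bg$sdlog)
  lapply(seq_len(n), function(i) {
    sp <- compoundSpec(sprintf("background%03d", i), "", rt_apex = rt[i],
                       base_abundance = ab[i],
                       dose_response = c(Blank = 1, Low = 1, High = 1),
                       class = "background", origin = "background")
    sp$fixed_mz <- mz[i]  # background species have no assigned composition
    sp
  })
}

# Gaussian chromatographic trace of one ion on the scan grid.
# Returns data.frame(scan, rt, mz, intensity) or NULL.
.ionTrace <- function(area, mz, rt_apex, rt_sigma, grid, noise,
                      driftFactor, minIntensity = 0.1) {
  rts <- seq(grid$rt_min, grid$rt_max, by = grid$interval)
  keep <- which(abs(rts - rt_apex) <= 4 * rt_sigma)
  if (!length(keep)) return(NULL)
  intensity <- area * stats::dnorm(rts[keep], rt_apex, rt_sigma) * driftFactor
  if (noise$intensity_cv > 0)
    intensity <- intensity *
      exp(stats::rnorm(length(intensity), 0, noise$intensity_cv))
  ok <- intensity >= minIntensity
  if (!any(ok)) return(NULL)
  keep <- keep[ok]; intensity <- intensity[ok]
  mzs <- mz * (1 + stats::rnorm(length(keep), 0, noise$sigma_ppm) * 1e-6)
  data.frame(scan = keep, rt = rts[keep], mz = mzs, intensity = intensity)
}

#' Simulate one LC-MS injection
#'
#' Each active species contributes a Gaussian chromatographic profile per
#' adduct ion, with 13C isotopologue traces at +k*1.003355/z for k = 1, 2
#' (M+1/M ~ nC x 0.0107, M+2 by the binomial approximation), centroid m/z
#' jitter ~ Normal(0, sigma_ppm), a run-wide multiplicative sensitivity
#' factor (1 + drift_rate x injection_index), sparse additive noise
#' centroids at uniform random m/z with log-normal intensities, and a small
#' dose-independent "chemical bleed" area at each substrate-derived species'
#' coordinates (so that reintegrating a blank region returns noise, as real
#' chromatograms do).
#'
#' @param species list of [compoundSpec()] objects (background species may
#'   carry \code{fixed_mz} instead of a formula).
#' @param group incubation group of the run.
#' @param sampleType run type (see \linkS4class{SpectrumRun}).
#' @param injectionIndex 1-based sequence position.
#' @param scenario scenario list providing \code{grid}, \code{noise} and
#'   \code{drift_rate}.
#' @param sampleId sample identifier.
#' @param seed optional seed; by default the current RNG stream is used so
#'   that [simulateStudy()] is reproducible from a single master seed.
#' @return list with elements \code{run} (a \linkS4class{SpectrumRun}) and
#'   \code{ledger} (data.frame of planted species, one row per active
#'   species: name, class, adduct, mz, rt_apex, abundance planted pre-drift
#'   including bleed, dose_abundance excluding bleed, multiplier).
#' @export
simulateRun <- function(species, group, sampleType, injectionIndex,
                        scenario, sampleId = "sample", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- scenario$grid
  noise <- scenario$noise
  if (is.null(grid) || grid$interval <= 0 || grid$rt_max <= grid$rt_min)
    stop("empty scan grid: rt_max must exceed rt_min with a positive interval")
  rts <- seq(grid$rt_min, grid$rt_max, by = grid$interval)
  driftFactor <- 1 + scenario$drift_rate * injectionIndex
  traces <- list()
  ledger <- list()
  for (sp in species) {
    mult <- .speciesMultiplier(sp, group, sampleType)
    bleed <- 0
    if (noise$bleed_area > 0 && sp$origin != "background")
      bleed <- stats::rlnorm(1, log(noise$bleed_area), noise$bleed_sdlog)
    for (ai in seq_along(sp$adducts)) {
      frac <- sp$adducts[[ai]]
      doseArea <- sp$base_abundance * frac * mult
      totalArea <- doseArea + bleed * frac
      if (totalArea <= 0) next
      if (!is.null(sp$fixed_mz)) {
        mzMain <- sp$fixed_mz
        nC <- 0L
        zAbs <- 1L
      } else {
        ion <- parseIonSpecies(names(sp$adducts)[ai])
        mzMain <- ionMz(monoisotopicMass(sp$formula), ion)
        nC <- ion@multiplicity *
          as.integer(c(parseFormula(sp$formula)["C"]))
        if (is.na(nC)) nC <- 0L
        zAbs <- abs(ion@charge)
      }
      ratios <- c(1, nC * 0.0107, choose(nC, 2) * 0.0107^2)
      for (k in 0:2) {
        if (ratios[k + 1] <= 0) next
        area_k <- totalArea * ratios[k + 1]
        tr <- .ionTrace(area_k, mzMain + k * c13Spacing() / zAbs,
                        sp$rt_apex, sp$rt_sigma, grid, noise, driftFactor)
        if (!is.null(tr)) traces[[length(traces) + 1L]] <- tr
        if (k == 0L)
          ledger[[length(ledger) + 1L]] <- data.frame(
            sample_id = sampleId, species = sp$name, class = sp$class,
            adduct = names(sp$adducts)[ai], mz = mzMain,
            rt_apex = sp$rt_apex, abundance = totalArea,
            dose_abundance = doseArea, multiplier = mult)
      }
    }
  }
  # sparse uniform noise centroids
  if (noise$density > 0) {
    nPer <- stats::rpois(length(rts), noise$density)
    tot <- sum(nPer)
    if (tot > 0) {
      scan <- rep(seq_along(rts), nPer)
      traces[[length(traces) + 1L]] <- data.frame(
        scan = scan, rt = rts[scan],
        mz = stats::runif(tot, 50, 750),
        intensity = stats::rlnorm(tot, noise$meanlog, noise$sdlog))
    }
  }
  cents <- if (length(traces)) do.call(rbind, traces) else
    data.frame(scan = integer(), rt = numeric(), mz = numeric(),
               intensity = numeric())
  run <- SpectrumRun(cents, sampleId = sampleId, group = group,
                     sampleType = sampleType,
                     injectionIndex = injectionIndex)
  ledger <- if (length(ledger)) do.call(rbind, ledger) else NULL
  list(run = run, ledger = ledger)
}

#' Build the randomized injection sequence of a study
#'
#' QC lead-in injections open the sequence, then the randomized incubation
#' samples with one QC after every \code{qc_every} samples, then the
#' substrate-blank and enzyme-blank runs. Injection indices are continuous
#' over the whole sequence.
#'
#' @param design design list (replicates, qc_lead_in, qc_every,
#'   n_substrate_blank, n_enzyme_blank).
#' @return data.frame with columns sample_id, group, sample_type,
#'   injection_index.
#' @export
designSequence <- function(design) {
  groups <- rep(c("Blank", "Low", "High"), each = design$replicates)
  ids <- paste0(groups, "_", sequence(rep(design$replicates, 3)))
  ord <- sample(length(ids))  # randomized injection order for samples
  groups <- groups[ord]; ids <- ids[ord]
  rows <- list()
  addRow <- function(id, grp, type) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = id, group = grp, sample_type = type)
  }
  for (i in seq_len(design$qc_lead_in)) addRow(paste0("QC_", i), "QC", "qc")
  nQc <- design$qc_lead_in
  for (i in seq_along(ids)) {
    addRow(ids[i], groups[i], "incubation")
    if (i %% design$qc_every == 0 && i < length(ids) + 1) {
      nQc <- nQc + 1L
      addRow(paste0("QC_", nQc), "QC", "qc")
    }
  }
  for (i in seq_len(design$n_substrate_blank))
    addRow(paste0("SubstrateBlank_", i), "Blank", "substrate_blank")
  for (i in seq_len(design$n_enzyme_blank))
    addRow(paste0("EnzymeBlank_", i), "Blank", "enzyme_blank")
  out <- do.call(rbind, rows)
  out$injection_index <- seq_len(nrow(out))
  out
}

#' Simulate a complete incubation study
#'
#' Draws the background-species inventory, builds the randomized injection
#' sequence and simulates every run. Deterministic under a fixed scenario
#' seed; two different seeds give different injection orders and noise but
#' an identical species inventory structure.
#'
#' @param scenario scenario list, see [defaultScenario()].
#' @param seed optional override of \code{scenario$seed}.
#' @return list with elements \code{runs} (named list of
#'   \linkS4class{SpectrumRun}), \code{ledger} (data.frame over all runs),
#'   \code{design} (injection sequence), \code{species} (full species list)
#'   and \code{scenario}.
#' @export
simulateStudy <- function(scenario = defaultScenario(), seed = NULL) {
  if (is.null(seed)) seed <- scenario$seed
  if (scenario$design$replicates < 2L)
    stop("at least 2 replicates per group are required for group comparisons")
  set.seed(seed)
  species <- c(scenario$species, .backgroundSpecies(scenario))
  design <- designSequence(scenario$design)
  runs <- vector("list", nrow(design))
  ledgers <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    res <- simulateRun(species, group = design$group[i],
                       sampleType = design$sample_type[i],
                       injectionIndex = design$injection_index[i],
                       scenario = scenario,
                       sampleId = design$sample_id[i])
    runs[[i]] <- res$run
    ledgers[[i]] <- res$ledger
  }
  names(runs) <- design$sample_id
  list(runs = runs, ledger = do.call(rbind, ledgers), design = design,
       species = species, scenario = scenario)
}
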