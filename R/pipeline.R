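# Pipeline orchestration: configuration with the workflow's default
# thresholds, stage sequencing, logging, manifest and CSV artifact export.

#' Assemble a pipeline configuration
#'
#' Central configuration with the workflow defaults: fold-change threshold
#' 1.5, p-value threshold 0.001, retention-time window 60-600 s, 5 ppm
#' annotation tolerance. Unknown keys are rejected.
#'
#' @param scenario simulation scenario (see [defaultScenario()]).
#' @param peaks list of peak-detection parameters: ppm_tol, min_scans,
#'   max_gap, snr_min, width_bounds, group_ppm, group_rt_tol, fill_ppm.
#' @param stats list: fc_thresh, p_thresh, rt_window.
#' @param drift list: exclude_qc (sample ids), enabled.
#' @param mva list: perplexity, tsne_iter, tsne_seed.
#' @param annotate list: ppm_tol, rt_tol, presence_factor, presence_frac.
#' @param seed master seed; every random draw of a pipeline run flows from
#'   it.
#' @return a validated configuration list of class "PipelineConfig".
#' @export
pipelineConfig <- function(scenario = defaultScenario(),
                           peaks = list(), stats = list(),
                           drift = list(), mva = list(),
                           annotate = list(), seed = 42) {
  defaults <- list(
    peaks = list(ppm_tol = 10, min_scans = 5, max_gap = 2, snr_min = 3,
                 width_bounds = c(3, 60), group_ppm = 5, group_rt_tol = 10,
                 fill_ppm = 10),
    stats = list(fc_thresh = 1.5, p_thresh = 0.001, rt_window = c(60, 600)),
    drift = list(exclude_qc = character(), enabled = TRUE),
    mva = list(perplexity = 5, tsne_iter = 1000, tsne_seed = 42),
    annotate = list(ppm_tol = 5, rt_tol = 10, presence_factor = 3,
                    presence_frac = 0.1))
  merge1 <- function(base, user, where) {
    bad <- setdiff(names(user), names(base))
    if (length(bad))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
    base[names(user)] <- user
    base
  }
  cfg <- list(
    scenario = scenario,
    peaks = merge1(defaults$peaks, peaks, "peaks"),
    stats = merge1(defaults$stats, stats, "stats"),
    drift = merge1(defaults$drift, drift, "drift"),
    mva = merge1(defaults$mva, mva, "mva"),
    annotate = merge1(defaults$annotate, annotate, "annotate"),
    seed = seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; changes iff any parameter
#' changes.
#' @param config a "PipelineConfig".
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  cfg <- unclass(config)
  cfg$scenario$species <- lapply(cfg$scenario$species, unclass)
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12,
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the complete untargeted-metabolomics pipeline
#'
#' Executes, in order: study simulation (or a supplied set of runs), peak
#' detection and feature grouping, missing-region reintegration, the
#' fold-change/Welch-t/retention-time significance filter, zero replacement
#' and log10 transformation, QC-anchored drift correction, multivariate
#' diagnostics (PCA, t-SNE, hierarchical clustering) and feature
#' annotation. A stage failure aborts with the stage name; artifacts of the
#' completed stages are retained in the error condition's \code{partial}
#' field.
#'
#' @param config a [pipelineConfig()].
#' @param study optional precomputed [simulateStudy()] result; simulated
#'   from \code{config$scenario} when NULL.
#' @param outDir optional directory for CSV artifacts and the run manifest.
#' @param verbose print per-stage feature accounting.
#' @return list with elements study, features (all features), comparisons,
#'   verdicts, filtered, processed (filtered + log10 + corrected assays),
#'   drift_models, qc_report, pca, tsne, clustering, annotations, manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), study = NULL,
                        outDir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  timings <- c()
  partial <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      e2 <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                conditionMessage(e)))
      e2$partial <- partial
      stop(e2)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    res
  }

  study <- if (is.null(study))
    stage("simulate", simulateStudy(config$scenario, seed = config$seed))
  else study
  partial$study <- study
  say("simulate: %d runs, %d planted species rows", length(study$runs),
      nrow(study$ledger))
  if (!"Blank" %in% study$design$group)
    stop("group 'Blank' is missing from the study design")

  pk <- config$peaks
  interval <- study$scenario$grid$interval
  peaks <- stage("peaks", {
    pl <- lapply(study$runs, detectPeaksRun, ppm_tol = pk$ppm_tol,
                 min_scans = pk$min_scans, max_gap = pk$max_gap,
                 snr_min = pk$snr_min, width_bounds = pk$width_bounds,
                 interval = interval)
    do.call(rbind, c(pl, list(make.row.names = FALSE)))
  })
  say("peaks: %d peaks detected across %d runs", nrow(peaks),
      length(study$runs))

  fset <- stage("group", {
    sd <- study$design
    sd$polarity <- "pos"
    groupFeatures(peaks, sd, mz_ppm_tol = pk$group_ppm,
                  rt_tol = pk$group_rt_tol)
  })
  fset <- stage("fill", fillMissing(fset, study$runs,
                                    ppm_tol = pk$fill_ppm,
                                    interval = interval))
  partial$features <- fset
  say("group/fill: %d features x %d samples (%.1f%% filled)",
      nrow(fset), ncol(fset), 100 * mean(isFilled(fset)))

  st <- config$stats
  filt <- stage("filter",
                applyFilters(fset, fc_thresh = st$fc_thresh,
                             p_thresh = st$p_thresh,
                             rt_window = st$rt_window))
  partial$filtered <- filt
  say("filter: %d of %d features significant (|FC| > %.1f, p < %g, rt in [%g, %g])",
      sum(filt$verdicts$passed), nrow(fset), st$fc_thresh, st$p_thresh,
      st$rt_window[1], st$rt_window[2])
  if (!nrow(filt$fset)) stop("no features survive the significance filter")

  proc <- stage("transform", transformAbundances(filt$fset))
  models <- NULL
  qcReport <- NULL
  if (config$drift$enabled) {
    models <- stage("drift_fit",
                    fitDrift(proc, exclude_qc = config$drift$exclude_qc))
    proc <- stage("drift_correct", correctDrift(proc, models))
    qcReport <- qcDiagnostics(proc, proc, models)
    say("drift: %d of %d features eligible; QC CV improved for %.0f%%",
        sum(models$eligible), nrow(models),
        100 * qcReport$improved_fraction)
  } else {
    assay(proc, "corrected", withDimnames = FALSE) <-
      abundances(proc, "log10")
  }
  partial$processed <- proc

  mv <- config$mva
  pca <- stage("pca", runPCA(proc))
  tsne <- stage("tsne", runTSNE(proc, perplexity = mv$perplexity,
                                max_iter = mv$tsne_iter,
                                seed = mv$tsne_seed))
  clustering <- stage("hclust", hclustHeatmap(proc))
  say("mva: PC1 explains %.1f%% of the variance",
      pca$variance_explained[1])

  an <- config$annotate
  annotations <- stage("annotate",
    annotateFeatures(filt$fset, study$scenario$parent_formula,
                     ppm_tol = an$ppm_tol, rt_tol = an$rt_tol,
                     comparisons = filt$comparisons,
                     fc_thresh = st$fc_thresh, p_thresh = st$p_thresh,
                     presence_factor = an$presence_factor,
                     presence_frac = an$presence_frac))
  say("annotate: %s", paste(sprintf("%d %s", table(annotations$class),
                                    names(table(annotations$class))),
                            collapse = ", "))

  manifest <- list(
    seed = config$seed,
    config_hash = configHash(config),
    n_runs = length(study$runs),
    n_features = nrow(fset),
    n_significant = sum(filt$verdicts$passed),
    stage_seconds = as.list(timings),
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(study = study, features = fset,
                 comparisons = filt$comparisons,
                 verdicts = filt$verdicts, filtered = filt$fset,
                 processed = proc, drift_models = models,
                 qc_report = qcReport, pca = pca, tsne = tsne,
                 clustering = clustering, annotations = annotations,
                 manifest = manifest)
  if (!is.null(outDir)) writePipelineOutputs(result, outDir)
  result
}

#' Write the CSV artifact bundle of a pipeline run
#'
#' CSV dialect: comma separated, UTF-8, "." decimal, header row. Timings in
#' the manifest are the only non-deterministic fields.
#'
#' @param result a [runPipeline()] result.
#' @param outDir output directory (created if needed).
#' @return invisibly, \code{outDir}.
#' @export
writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outDir, f)
  writeFeatureTable(result$features, fp("feature_table.csv"))
  utils::write.csv(result$comparisons, fp("comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(result$verdicts, fp("verdicts.csv"), row.names = FALSE)
  writeFeatureTable(result$processed, fp("corrected_table.csv"),
                    assayName = "corrected")
  if (!is.null(result$drift_models))
    utils::write.csv(result$drift_models, fp("drift_models.csv"),
                     row.names = FALSE)
  pcaScores <- data.frame(sample_id = rownames(result$pca$scores),
                          group = result$pca$groups,
                          result$pca$scores[, 1:2, drop = FALSE])
  utils::write.csv(pcaScores, fp("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(component = seq_along(result$pca$variance_explained),
               variance_explained = result$pca$variance_explained),
    fp("pca_variance.csv"), row.names = FALSE)
  cd <- sampleInfo(result$processed)
  utils::write.csv(
    data.frame(sample_id = cd$sample_id[cd$sample_type %in%
                                          c("incubation", "qc")],
               group = result$tsne$groups,
               tsne1 = result$tsne$embedding[, 1],
               tsne2 = result$tsne$embedding[, 2]),
    fp("tsne.csv"), row.names = FALSE)
  utils::write.csv(result$annotations, fp("annotations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Volcano plot of group comparisons
#'
#' Fold change (signed) versus -log10 p for one group comparison, with the
#' filter thresholds drawn as reference lines.
#'
#' @param comparisons a [compareGroups()] result.
#' @param comparison which comparison to plot (default "Blank-High").
#' @param fc_thresh,p_thresh thresholds to draw.
#' @return a ggplot object.
#' @export
volcanoPlot <- function(comparisons, comparison = "Blank-High",
                        fc_thresh = 1.5, p_thresh = 0.001) {
  df <- comparisons[comparisons$comparison == comparison, ]
  df <- df[is.finite(df$fold_change) & df$p > 0, ]
  df$significant <- abs(df$fold_change) > fc_thresh & df$p < p_thresh
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_change,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(p_thresh),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-fc_thresh, fc_thresh),
                        linetype = "dashed") +
    ggplot2::labs(x = "signed fold change", y = "-log10 p",
                  title = comparison) +
    ggplot2::theme_minimal()
}

#' QC drift trend of one feature, before and after correction
#'
#' @param fset a corrected \linkS4class{FeatureSet} (assays "log10" and
#'   "corrected").
#' @param feature feature name to plot.
#' @return a ggplot object.
#' @export
qcTrendPlot <- function(fset, feature) {
  cd <- sampleInfo(fset)
  qc <- cd$sample_type == "qc"
  df <- rbind(
    data.frame(injection = cd$injection_index[qc],
               log10_abundance = abundances(fset, "log10")[feature, qc],
               stage = "before"),
    data.frame(injection = cd$injection_index[qc],
               log10_abundance = abundances(fset, "corrected")[feature, qc],
               stage = "after"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$injection,
                                   y = .data$log10_abundance,
                                   colour = .data$stage)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "injection index", y = "log10 abundance",
                  title = feature) +
    ggplot2::theme_minimal()
}
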