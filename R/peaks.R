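# Chromatographic peak detection in centroided runs, cross-sample feature
# grouping, and reintegration of missing regions.

#' Build extracted-ion traces (regions of interest) from a centroided run
#'
#' Greedy m/z-trace building over the scan grid: within each scan, a
#' centroid joins an open ROI if it lies within \code{ppm_tol} of the ROI's
#' running mean m/z (nearest ROI wins); otherwise it opens a new ROI. ROIs
#' not extended for more than \code{max_gap} scans are closed. ROIs spanning
#' fewer than \code{min_scans} distinct scans are discarded.
#'
#' @param run a \linkS4class{SpectrumRun}.
#' @param ppm_tol m/z tolerance in ppm for joining a trace.
#' @param min_scans minimum number of distinct scans per kept ROI.
#' @param max_gap maximum number of consecutive scans an ROI may miss before
#'   it is closed.
#' @return list of EIC objects: each a list with \code{mz} (mean m/z) and
#'   \code{points} (data.frame scan, rt, mz, intensity).
#' @export
extractRois <- function(run, ppm_tol = 10, min_scans = 5, max_gap = 2) {
  cc <- centroids(run)
  n <- nrow(cc)
  if (!n) return(list())
  roiId <- integer(n)
  # open-ROI state
  cap <- 256L
  o_mz <- numeric(cap); o_n <- integer(cap); o_last <- integer(cap)
  o_id <- integer(cap); nOpen <- 0L; nextId <- 1L
  scans <- cc$scan
  byScan <- split(seq_len(n), factor(scans, levels = sort(unique(scans))))
  for (sc in names(byScan)) {
    scanNo <- as.integer(sc)
    idx <- byScan[[sc]]
    ptMz <- cc$mz[idx]
    if (nOpen > 0L) {
      keepOpen <- o_last[seq_len(nOpen)] >= scanNo - max_gap - 1L
      if (!all(keepOpen)) {
        kept <- which(keepOpen)
        o_mz[seq_along(kept)] <- o_mz[kept]
        o_n[seq_along(kept)] <- o_n[kept]
        o_last[seq_along(kept)] <- o_last[kept]
        o_id[seq_along(kept)] <- o_id[kept]
        nOpen <- length(kept)
      }
    }
    if (nOpen > 0L) {
      ord <- order(o_mz[seq_len(nOpen)])
      sMz <- o_mz[seq_len(nOpen)][ord]
      pos <- findInterval(ptMz, sMz)
      lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, nOpen)
      dLo <- abs(ptMz - sMz[lo]); dHi <- abs(ptMz - sMz[hi])
      nearest <- ifelse(dLo <= dHi, lo, hi)
      dist <- pmin(dLo, dHi)
      match_ok <- dist <= ptMz * ppm_tol * 1e-6 & pos >= 0L
      slot <- ifelse(match_ok, ord[nearest], NA_integer_)
    } else slot <- rep(NA_integer_, length(ptMz))
    for (j in seq_along(idx)) {
      if (!is.na(slot[j])) {
        s <- slot[j]
        roiId[idx[j]] <- o_id[s]
        o_mz[s] <- o_mz[s] + (ptMz[j] - o_mz[s]) / (o_n[s] + 1L)
        o_n[s] <- o_n[s] + 1L
        o_last[s] <- scanNo
      } else {
        nOpen <- nOpen + 1L
        if (nOpen > cap) {
          cap <- cap * 2L
          length(o_mz) <- cap; length(o_n) <- cap
          length(o_last) <- cap; length(o_id) <- cap
        }
        o_mz[nOpen] <- ptMz[j]; o_n[nOpen] <- 1L
        o_last[nOpen] <- scanNo; o_id[nOpen] <- nextId
        roiId[idx[j]] <- nextId
        nextId <- nextId + 1L
      }
    }
  }
  # keep ROIs with enough distinct scans
  grpIdx <- split(seq_len(n), roiId)
  keep <- vapply(grpIdx, function(ii) length(unique(scans[ii])) >= min_scans,
                 logical(1))
  lapply(grpIdx[keep], function(ii) {
    pts <- cc[ii, c("scan", "rt", "mz", "intensity")]
    rownames(pts) <- NULL
    structure(list(mz = mean(pts$mz), points = pts), class = "EIC")
  })
}

# Aggregate EIC member points onto a complete local rt grid (zeros where no
# point), padded by `pad` scans on both sides.
.eicGrid <- function(eic, interval, pad = 10L) {
  pts <- eic$points
  s0 <- min(pts$scan) - pad; s1 <- max(pts$scan) + pad
  scans <- s0:s1
  y <- numeric(length(scans))
  agg <- tapply(pts$intensity, pts$scan, sum)
  y[match(as.integer(names(agg)), scans)] <- agg
  rt0 <- pts$rt[1] - (pts$scan[1] - s0) * interval
  list(scans = scans, rt = rt0 + (scans - s0) * interval, y = y)
}

.gaussSmooth <- function(y, sd = 2) {
  half <- ceiling(3 * sd)
  k <- stats::dnorm(-half:half, 0, sd)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(0, half), y, rep(0, half))
  vapply(seq_len(n), function(i) sum(ypad[i:(i + 2 * half)] * k), numeric(1))
}

#' Detect chromatographic peaks in one extracted-ion trace
#'
#' The trace is smoothed with a small Gaussian kernel; local maxima with a
#' signal-to-noise ratio of at least \code{snr_min} (noise estimated from
#' the median absolute deviation of the raw-minus-smoothed residual, with a
#' floor of one count) become peak apices. Peak bounds are placed at the
#' nearest flanking local minima, the width must fall inside
#' \code{width_bounds}, and the area is integrated by the trapezoid rule on
#' the raw trace.
#'
#' @param eic an EIC from [extractRois()].
#' @param snr_min minimum signal-to-noise ratio.
#' @param width_bounds numeric length-2, allowed peak width (seconds) at the
#'   bounding minima.
#' @param interval scan interval of the run's grid (seconds).
#' @param sample_id sample identifier copied into the peak rows.
#' @return data.frame of peaks: sample_id, mz (intensity-weighted apex m/z),
#'   rt (apex), rt_lo, rt_hi, area, snr, apex_intensity. Zero rows if none.
#' @export
detectPeaks <- function(eic, snr_min = 3, width_bounds = c(3, 60),
                        interval = 0.5, sample_id = "sample") {
  if (length(width_bounds) != 2L || any(!is.finite(width_bounds)) ||
      width_bounds[1] >= width_bounds[2] || width_bounds[1] < 0)
    stop("width_bounds must be an increasing, non-negative length-2 vector")
  g <- .eicGrid(eic, interval)
  y <- g$y
  if (!any(y > 0)) return(.emptyPeaks())
  ys <- .gaussSmooth(y)
  baseline <- stats::median(ys)
  noise <- max(stats::mad(y - ys), 1)
  n <- length(ys)
  isMax <- which(ys > c(-Inf, ys[-n]) & ys >= c(ys[-1], -Inf))
  rows <- list()
  for (im in isMax) {
    snr <- (ys[im] - baseline) / noise
    if (snr < snr_min) next
    # walk to the flanking local minima of the smoothed trace, stopping
    # once the signal has decayed to ~1% of the apex above baseline (so an
    # isolated peak is bounded near its feet, not at the trace edges)
    floorInt <- baseline + 0.01 * (ys[im] - baseline)
    lo <- im
    while (lo > 1L && ys[lo - 1L] < ys[lo] && ys[lo] > floorInt)
      lo <- lo - 1L
    hi <- im
    while (hi < n && ys[hi + 1L] < ys[hi] && ys[hi] > floorInt)
      hi <- hi + 1L
    width <- g$rt[hi] - g$rt[lo]
    if (width < width_bounds[1] || width > width_bounds[2]) next
    area <- sum(diff(g$rt[lo:hi]) *
                  (utils::head(y[lo:hi], -1) + y[(lo + 1L):hi]) / 2)
    if (area <= 0) next
    inb <- eic$points$scan >= g$scans[lo] & eic$points$scan <= g$scans[hi]
    apexMz <- if (any(inb))
      stats::weighted.mean(eic$points$mz[inb], eic$points$intensity[inb])
    else eic$mz
    apexIdx <- lo - 1L + which.max(y[lo:hi])
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample_id, mz = apexMz, rt = g$rt[apexIdx],
      rt_lo = g$rt[lo], rt_hi = g$rt[hi], area = area, snr = snr,
      apex_intensity = y[apexIdx])
  }
  if (!length(rows)) return(.emptyPeaks())
  do.call(rbind, rows)
}

.emptyPeaks <- function() {
  data.frame(sample_id = character(), mz = numeric(), rt = numeric(),
             rt_lo = numeric(), rt_hi = numeric(), area = numeric(),
             snr = numeric(), apex_intensity = numeric())
}

#' Detect all peaks of one run
#' @param run a \linkS4class{SpectrumRun}.
#' @param ppm_tol,min_scans,max_gap passed to [extractRois()].
#' @param snr_min,width_bounds passed to [detectPeaks()].
#' @param interval scan interval (seconds).
#' @return data.frame of peaks over all ROIs of the run.
#' @export
detectPeaksRun <- function(run, ppm_tol = 10, min_scans = 5, max_gap = 2,
                           snr_min = 3, width_bounds = c(3, 60),
                           interval = 0.5) {
  rois <- extractRois(run, ppm_tol = ppm_tol, min_scans = min_scans,
                      max_gap = max_gap)
  if (!length(rois)) return(.emptyPeaks())
  out <- lapply(rois, detectPeaks, snr_min = snr_min,
                width_bounds = width_bounds, interval = interval,
                sample_id = run@sampleId)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Group per-sample peaks into cross-sample features
#'
#' Peaks are clustered by single-linkage: first along m/z (splitting where
#' the gap between mz-ordered neighbours exceeds \code{mz_ppm_tol}), then
#' along retention time within each m/z cluster (splitting at gaps larger
#' than \code{rt_tol}). Within a cluster, duplicates from the same sample
#' are resolved by keeping the larger area. Consensus m/z and rt are the
#' medians of the member peaks; the consensus integration window is the
#' median of the member bounds. Peaks are pre-sorted by (sample_id, rt) so
#' that ties break deterministically, and the result is invariant to sample
#' processing order.
#'
#' @param peaks data.frame of peaks from [detectPeaksRun()] (rows from all
#'   samples bound together).
#' @param sampleData data.frame of per-sample metadata with a
#'   \code{sample_id} column plus group, sample_type, injection_index.
#' @param mz_ppm_tol m/z gap tolerance (ppm).
#' @param rt_tol retention-time gap tolerance (seconds).
#' @return a \linkS4class{FeatureSet} (abundance 0 where a sample has no
#'   member peak).
#' @export
groupFeatures <- function(peaks, sampleData, mz_ppm_tol = 5, rt_tol = 10) {
  stopifnot("sample_id" %in% names(sampleData))
  peaks <- peaks[order(peaks$sample_id, peaks$rt), , drop = FALSE]
  ord <- order(peaks$mz)
  p <- peaks[ord, , drop = FALSE]
  n <- nrow(p)
  if (!n) stop("no peaks to group")
  gap <- diff(p$mz) / p$mz[-n] > mz_ppm_tol * 1e-6
  mzCluster <- cumsum(c(TRUE, gap))
  cluster <- integer(n)
  nextCl <- 0L
  for (cl in split(seq_len(n), mzCluster)) {
    o <- cl[order(p$rt[cl])]
    sub <- cumsum(c(TRUE, diff(p$rt[o]) > rt_tol))
    cluster[o] <- nextCl + sub
    nextCl <- nextCl + max(sub)
  }
  sampleIds <- as.character(sampleData$sample_id)
  rows <- list()
  for (cl in split(seq_len(n), cluster)) {
    sub <- p[cl, , drop = FALSE]
    # per-sample duplicates: keep the larger area
    sub <- sub[order(sub$sample_id, -sub$area), , drop = FALSE]
    sub <- sub[!duplicated(sub$sample_id), , drop = FALSE]
    ab <- stats::setNames(numeric(length(sampleIds)), sampleIds)
    ab[sub$sample_id] <- sub$area
    rows[[length(rows) + 1L]] <- list(
      mz = stats::median(sub$mz), rt = stats::median(sub$rt),
      rt_lo = stats::median(sub$rt_lo), rt_hi = stats::median(sub$rt_hi),
      n_detected = nrow(sub), abundance = ab)
  }
  mzs <- vapply(rows, `[[`, numeric(1), "mz")
  rts <- vapply(rows, `[[`, numeric(1), "rt")
  o <- order(mzs, rts)
  rows <- rows[o]
  fd <- data.frame(
    mz = mzs[o], rt = rts[o],
    rt_lo = vapply(rows, `[[`, numeric(1), "rt_lo"),
    rt_hi = vapply(rows, `[[`, numeric(1), "rt_hi"),
    n_detected = vapply(rows, function(r) as.integer(r$n_detected),
                        integer(1)))
  fd$name <- featureName(fd$mz, fd$rt)
  ab <- do.call(rbind, lapply(rows, `[[`, "abundance"))
  rownames(ab) <- make.unique(fd$name)
  FeatureSet(ab, featureData = fd, sampleData = sampleData)
}

# integrate the raw signal of `run` in an m/z +/- ppm window over
# [rt_lo, rt_hi], trapezoid on the complete scan grid within the window
.integrateWindow <- function(run, mz, ppm, rt_lo, rt_hi, interval) {
  cc <- centroids(run)
  tol <- mz * ppm * 1e-6
  sel <- cc$mz >= mz - tol & cc$mz <= mz + tol &
    cc$rt >= rt_lo & cc$rt <= rt_hi
  scans <- seq(floor(rt_lo / interval), ceiling(rt_hi / interval))
  y <- numeric(length(scans))
  if (any(sel)) {
    agg <- tapply(cc$intensity[sel], round(cc$rt[sel] / interval), sum)
    hit <- match(as.integer(names(agg)), scans)
    ok <- !is.na(hit)
    y[hit[ok]] <- agg[ok]
  }
  if (length(y) < 2L) return(sum(y) * interval)
  sum(interval * (utils::head(y, -1) + y[-1]) / 2)
}

#' Reintegrate features in samples where they were not detected
#'
#' For every feature/sample cell without a detected peak, the raw signal of
#' that sample is integrated over the feature's consensus retention-time
#' window and m/z tolerance. Where the sample genuinely lacks the compound
#' this integrates noise, deliberately reproducing the high blank-group
#' variance that region reintegration causes in real studies. Filled cells
#' are marked in the \code{"filled"} assay.
#'
#' @param fset a \linkS4class{FeatureSet} from [groupFeatures()].
#' @param runs named list of \linkS4class{SpectrumRun} (names = sample ids).
#' @param ppm_tol m/z half-window in ppm.
#' @param interval scan interval (seconds).
#' @return the updated \linkS4class{FeatureSet}.
#' @export
fillMissing <- function(fset, runs, ppm_tol = 10, interval = 0.5) {
  ab <- abundances(fset)
  fl <- isFilled(fset)
  rd <- rowData(fset)
  for (j in seq_len(ncol(ab))) {
    sid <- colnames(ab)[j]
    run <- runs[[sid]]
    if (is.null(run)) next
    miss <- which(ab[, j] == 0)
    for (i in miss) {
      ab[i, j] <- .integrateWindow(run, rd$mz[i], ppm_tol,
                                   rd$rt_lo[i], rd$rt_hi[i], interval)
      fl[i, j] <- TRUE
    }
  }
  assay(fset, "abundance") <- ab
  assay(fset, "filled") <- fl
  fset
}
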