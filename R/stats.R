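# Group-comparison statistics and the significance filter, in the stated
# order of operations: fold changes and Welch t-tests on the raw (untrans-
# formed) abundances, then the retention-time window, then zero replacement
# and log10 transformation.

#' Signed fold change between two group means
#'
#' The ratio \code{mean_b / mean_a} if it is at least 1, otherwise the
#' negative reciprocal, so that a threshold of "< -1.5 or > 1.5" is
#' symmetric. Degenerate cases: both means 0 gives \code{NA} (an undefined
#' sentinel that never passes the filter); one mean 0 gives a signed
#' infinity, which passes the fold-change criterion (the p-value still
#' gates).
#'
#' @param mean_a,mean_b non-negative group means (vectorized).
#' @return signed fold change(s).
#' @examples
#' signedFoldChange(100, 200) #  2
#' signedFoldChange(200, 100) # -2
#' @export
signedFoldChange <- function(mean_a, mean_b) {
  if (any(mean_a < 0 | mean_b < 0, na.rm = TRUE))
    stop("group means must be non-negative")
  out <- ifelse(mean_b >= mean_a, mean_b / mean_a, -mean_a / mean_b)
  out[mean_a == 0 & mean_b == 0] <- NA_real_
  out[mean_a == 0 & mean_b > 0] <- Inf
  out[mean_b == 0 & mean_a > 0] <- -Inf
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both samples have zero variance the
#' statistic degenerates: equal means give t = 0, p = 1; unequal means give
#' a signed infinite t with p = 0.
#'
#' @param x,y numeric vectors with at least 2 observations each.
#' @return list with elements \code{t}, \code{df}, \code{p}.
#' @examples
#' welchT(c(1, 2, 3), c(4, 5, 6)) # t ~ -3.674, df = 4, p ~ 0.0214
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mx == my) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(mx - my) * Inf, df = nx + ny - 2, p = 0))
  }
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# vectorized Welch over rows of two matrices (used for feature tables and
# the Monte-Carlo calibration)
.rowWelch <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- ifelse(se2 > 0, (mx - my) / sqrt(se2),
                  ifelse(mx == my, 0, sign(mx - my) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)),
               nx + ny - 2)
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df),
              ifelse(tstat == 0, 1, 0))
  p[tstat == 0] <- 1
  list(t = tstat, df = df, p = p)
}

#' Pairwise group comparisons of a feature table
#'
#' Computes, for every feature, the signed fold change and Welch t-test
#' p-value for the comparisons Blank-Low, Blank-High and Low-High, on the
#' raw abundances of the incubation samples.
#'
#' @param fset a \linkS4class{FeatureSet}.
#' @param assayName assay to test (default the raw "abundance").
#' @return data.frame with columns feature, comparison, mean_a, mean_b,
#'   fold_change, t, df, p.
#' @export
compareGroups <- function(fset, assayName = "abundance") {
  cd <- sampleInfo(fset)
  inc <- cd$sample_type == "incubation"
  ab <- abundances(fset, assayName)[, inc, drop = FALSE]
  grp <- cd$group[inc]
  for (g in c("Blank", "Low", "High"))
    if (sum(grp == g) < 2L)
      stop("group '", g, "' is missing or has fewer than 2 samples")
  pairs <- list(c("Blank", "Low"), c("Blank", "High"), c("Low", "High"))
  out <- lapply(pairs, function(pr) {
    A <- ab[, grp == pr[1], drop = FALSE]
    B <- ab[, grp == pr[2], drop = FALSE]
    w <- .rowWelch(A, B)
    data.frame(feature = rownames(ab),
               comparison = paste(pr, collapse = "-"),
               mean_a = rowMeans(A), mean_b = rowMeans(B),
               fold_change = signedFoldChange(rowMeans(A), rowMeans(B)),
               t = w$t, df = w$df, p = w$p, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Apply the significance filter to a feature table
#'
#' A feature is kept iff (i) in at least one of the three group comparisons
#' the absolute fold change exceeds \code{fc_thresh} AND the p-value of the
#' same comparison is below \code{p_thresh}, and (ii) its retention time
#' lies inside \code{rt_window} (inclusive on both ends). Statistics are
#' computed on raw abundances, zeros included, matching the stated order of
#' operations (transformation comes after filtering). No multiple-testing
#' correction is applied (the workflow gates on a raw p < 0.001).
#'
#' @param fset a \linkS4class{FeatureSet}.
#' @param fc_thresh absolute fold-change threshold (default 1.5).
#' @param p_thresh p-value threshold (default 0.001).
#' @param rt_window inclusive retention-time window in seconds (default
#'   c(60, 600); peaks outside elute during column equilibration/washing).
#' @param comparisons optional precomputed result of [compareGroups()].
#' @return list with \code{fset} (the filtered \linkS4class{FeatureSet}),
#'   \code{verdicts} (per-feature data.frame: feature, fc_p_pass,
#'   passing_comparison, rt_pass, passed) and \code{comparisons}.
#' @export
applyFilters <- function(fset, fc_thresh = 1.5, p_thresh = 0.001,
                         rt_window = c(60, 600), comparisons = NULL) {
  if (is.null(comparisons)) comparisons <- compareGroups(fset)
  cmp <- comparisons
  cmp$hit <- !is.na(cmp$fold_change) &
    abs(cmp$fold_change) > fc_thresh & cmp$p < p_thresh
  feats <- rownames(fset)
  hitBy <- tapply(cmp$hit, factor(cmp$feature, levels = feats), any)
  passCmp <- vapply(feats, function(f) {
    h <- cmp$comparison[cmp$feature == f & cmp$hit]
    if (length(h)) paste(h, collapse = ";") else NA_character_
  }, character(1))
  rt <- featureRt(fset)
  rtPass <- rt >= rt_window[1] & rt <= rt_window[2]
  verdicts <- data.frame(
    feature = feats,
    fc_p_pass = as.logical(hitBy),
    passing_comparison = passCmp,
    rt_pass = rtPass,
    passed = as.logical(hitBy) & rtPass,
    row.names = NULL)
  list(fset = fset[verdicts$passed, ], verdicts = verdicts,
       comparisons = comparisons)
}

#' Zero replacement and log10 transformation
#'
#' Every zero abundance is replaced by the smallest strictly positive
#' abundance of the whole table (a surrogate limit of detection), then the
#' table is log10 transformed. The result is stored in a new \code{"log10"}
#' assay; the raw assay is kept.
#'
#' @param fset a \linkS4class{FeatureSet}.
#' @return the \linkS4class{FeatureSet} with an added "log10" assay.
#' @export
transformAbundances <- function(fset) {
  ab <- abundances(fset)
  pos <- ab[ab > 0]
  if (!length(pos))
    stop("all abundances are zero; cannot derive a surrogate LOD")
  lod <- min(pos)
  ab[ab == 0] <- lod
  assay(fset, "log10", withDimnames = FALSE) <- log10(ab)
  fset
}
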