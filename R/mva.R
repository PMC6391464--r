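# Multivariate pattern analysis: PCA, exact t-SNE and hierarchical
# clustering with per-feature z-scores. Input matrices are samples x
# features (feature tables are transposed internally).

# pull a samples x features matrix from a FeatureSet or pass a matrix
# through; by default only incubation and QC samples enter the analysis
.mvaMatrix <- function(x, assayName = "corrected",
                       sample_types = c("incubation", "qc")) {
  if (is(x, "FeatureSet")) {
    cd <- sampleInfo(x)
    keep <- cd$sample_type %in% sample_types
    m <- t(abundances(x, assayName)[, keep, drop = FALSE])
    attr(m, "groups") <- cd$group[keep]
    m
  } else as.matrix(x)
}

#' Principal component analysis of a processed feature table
#'
#' Eigen-decomposition of the covariance of the column-centered data (no
#' scaling), via \code{stats::prcomp}. The sign of each component is fixed
#' deterministically by making its largest-magnitude loading positive.
#'
#' @param x a \linkS4class{FeatureSet} or a samples x features matrix.
#' @param assayName assay to analyse when \code{x} is a FeatureSet.
#' @param sample_types sample types entering the analysis.
#' @return list of class "PcaResult": \code{scores} (samples x components),
#'   \code{loadings} (features x components, orthonormal),
#'   \code{variance_explained} (percent, sums to 100 over all components),
#'   \code{groups} (sample group labels if known).
#' @export
runPCA <- function(x, assayName = "corrected",
                   sample_types = c("incubation", "qc")) {
  m <- .mvaMatrix(x, assayName, sample_types)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("PCA needs at least 2 samples and 2 features")
  if (all(apply(m, 2, stats::var) == 0))
    stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2) * 100
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve,
                 center = pc$center,
                 groups = attr(m, "groups")),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult:", nrow(x$scores), "samples,", nrow(x$loadings),
      "features\n")
  ve <- utils::head(x$variance_explained, 5)
  cat("  variance explained (%):",
      paste(sprintf("%.1f", ve), collapse = ", "),
      if (length(x$variance_explained) > 5) "...\n" else "\n")
  invisible(x)
}

# perplexity calibration: binary search for the Gaussian bandwidths
.tsneAffinities <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) sumP <- .Machine$double.eps
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      diffH <- H - logU
      if (abs(diffH) < tol) break
      if (diffH > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sum(Pi)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

#' t-distributed stochastic neighbour embedding (exact)
#'
#' Exact (non-tree-accelerated) t-SNE, adequate for the few dozen samples of
#' an incubation study. Gradient descent with momentum and early
#' exaggeration, deterministic under the given seed.
#'
#' @param x a \linkS4class{FeatureSet} or samples x features matrix.
#' @param perplexity target perplexity; must be below (n samples - 1).
#' @param max_iter gradient-descent iterations (default 1000).
#' @param seed RNG seed for the initial layout (default 42).
#' @param assayName,sample_types as in [runPCA()].
#' @return list of class "TsneResult": \code{embedding} (samples x 2),
#'   \code{groups}.
#' @export
runTSNE <- function(x, perplexity = 5, max_iter = 1000, seed = 42,
                    assayName = "corrected",
                    sample_types = c("incubation", "qc")) {
  m <- .mvaMatrix(x, assayName, sample_types)
  n <- nrow(m)
  if (perplexity >= n - 1)
    stop("perplexity must be smaller than the number of samples minus 1")
  D2 <- as.matrix(stats::dist(m))^2
  P <- .tsneAffinities(D2, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  eta <- 100
  exag <- 4
  Puse <- P * exag
  for (iter in seq_len(max_iter)) {
    if (iter == 101) Puse <- P
    if (iter == 251) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  structure(list(embedding = Y, groups = attr(m, "groups")),
            class = "TsneResult")
}

#' Mean silhouette width of an embedding by group label
#'
#' Simple silhouette computation (Euclidean) used to quantify how well an
#' embedding separates known groups.
#'
#' @param embedding samples x d coordinate matrix.
#' @param labels group label per sample.
#' @return mean silhouette width over all samples.
#' @export
groupSilhouette <- function(embedding, labels) {
  D <- as.matrix(stats::dist(embedding))
  labels <- as.character(labels)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Hierarchical clustering with per-feature z-scores
#'
#' Features are z-scored across samples (mean 0, sd 1); zero-variance
#' features are dropped with a warning. Samples and features are then
#' clustered agglomeratively (Euclidean distance, complete linkage), as for
#' a clustered heat map.
#'
#' @param x a \linkS4class{FeatureSet} or samples x features matrix.
#' @param assayName,sample_types as in [runPCA()].
#' @return list of class "ClusterResult": \code{z} (features x samples
#'   z-score matrix), \code{sample_hclust}, \code{feature_hclust},
#'   \code{sample_order}, \code{feature_order}, \code{groups}.
#' @export
hclustHeatmap <- function(x, assayName = "corrected",
                          sample_types = c("incubation", "qc")) {
  m <- .mvaMatrix(x, assayName, sample_types)  # samples x features
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance feature(s) dropped")
    m <- m[, v > 0, drop = FALSE]
  }
  z <- scale(m)                      # per feature across samples
  zs <- t(z)                         # features x samples
  hs <- stats::hclust(stats::dist(z), method = "complete")
  hf <- stats::hclust(stats::dist(zs), method = "complete")
  structure(list(z = zs, sample_hclust = hs, feature_hclust = hf,
                 sample_order = hs$order, feature_order = hf$order,
                 groups = attr(m, "groups")),
            class = "ClusterResult")
}
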