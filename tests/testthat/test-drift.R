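# QC-anchored linear drift models: fitting, correction, diagnostics.

# feature table with QC injections at the sequence positions of the default
# design (5 lead-in + every 5th), abundances following a multiplicative
# drift of `rate` per injection
.driftFset <- function(rate = -0.004, base = c(1e6, 2e5), ratioHigh = 2,
                       missingQc = FALSE) {
  qcIdx <- c(1:5, 11, 17, 23)
  smpIdx <- setdiff(1:23, qcIdx)
  inj <- c(qcIdx, smpIdx)
  groups <- c(rep("QC", 8), rep(c("Blank", "Low", "High"), each = 5))
  types <- c(rep("qc", 8), rep("incubation", 15))
  mult <- ifelse(groups == "High", ratioHigh, 1)
  ab <- rbind(
    base[1] * mult * (1 + rate * inj),
    base[2] * mult * (1 + rate * inj))
  fl <- matrix(FALSE, 2, length(inj))
  if (missingQc) { ab[2, 3] <- 0 }
  makeFset(ab, mz = c(218.15, 220.17), rt = c(216, 226), groups = groups,
           types = types, inj = inj, filled = fl)
}

test_that("drift slopes are recovered exactly on exact inputs", {
  # constant QC abundances -> slope 0
  fs <- .driftFset(rate = 0)
  fs <- transformAbundances(fs)
  m <- fitDrift(fs)
  expect_true(all(m$eligible))
  expect_lt(max(abs(m$slope)), 1e-12)
  # exactly linear log10 drift of -0.002 per injection
  fs2 <- .driftFset(rate = 0)
  ab <- abundances(fs2)
  inj <- sampleInfo(fs2)$injection_index
  ab <- ab * 10^(outer(c(-0.002, -0.002), inj))
  SummarizedExperiment::assay(fs2, "abundance") <- ab
  fs2 <- transformAbundances(fs2)
  m2 <- fitDrift(fs2)
  expect_equal(m2$slope, c(-0.002, -0.002), tolerance = 1e-10)
  # a feature undetected in one QC is ineligible
  fs3 <- transformAbundances(.driftFset(missingQc = TRUE))
  m3 <- fitDrift(fs3)
  expect_false(m3$eligible[2])
  expect_true(is.na(m3$slope[2]))
  # fewer than 3 QCs is an error
  fs4 <- fs[, 7:23]
  expect_error(fitDrift(transformAbundances(fs4)), "3 QC")
})

test_that("correction removes multiplicative drift and preserves ratios", {
  # zero slope -> identity
  fs0 <- transformAbundances(.driftFset(rate = 0))
  m0 <- fitDrift(fs0)
  fs0 <- correctDrift(fs0, m0)
  expect_equal(abundances(fs0, "corrected"), abundances(fs0, "log10"),
               tolerance = 1e-12)
  # -0.4%/injection drift, noise off
  fs <- transformAbundances(.driftFset(rate = -0.004))
  m <- fitDrift(fs)
  fs <- correctDrift(fs, m)
  qc <- sampleInfo(fs)$sample_type == "qc"
  cv <- function(x) sd(x) / mean(x)
  cvBefore <- apply(10^abundances(fs, "log10")[, qc], 1, cv)
  cvAfter <- apply(10^abundances(fs, "corrected")[, qc], 1, cv)
  expect_true(all(cvBefore >= 0.03))
  expect_true(all(cvAfter < 0.005))
  # planted High/Low group ratio recovered within 2%
  lin <- 10^abundances(fs, "corrected")
  grp <- sampleInfo(fs)$group
  ratio <- rowMeans(lin[, grp == "High"]) / rowMeans(lin[, grp == "Low"])
  expect_equal(unname(ratio), c(2, 2), tolerance = 0.02)
  # ineligible features pass through bit-identically
  fs3 <- transformAbundances(.driftFset(rate = -0.004, missingQc = TRUE))
  m3 <- fitDrift(fs3)
  fs3 <- correctDrift(fs3, m3)
  expect_identical(abundances(fs3, "corrected")[2, ],
                   abundances(fs3, "log10")[2, ])
})

test_that("QC diagnostics report improvement and flag outlier QCs", {
  fs <- transformAbundances(.driftFset(rate = -0.004))
  m <- fitDrift(fs)
  fsc <- correctDrift(fs, m)
  rep1 <- qcDiagnostics(fsc, fsc, m)
  expect_gte(rep1$improved_fraction, 0.9)
  expect_length(rep1$qc_outliers, 0)
  # identical before/after -> no improvement, all deltas zero
  same <- fsc
  SummarizedExperiment::assay(same, "corrected") <-
    abundances(same, "log10")
  rep2 <- qcDiagnostics(same, same, m)
  expect_identical(rep2$improved_fraction, 0)
  expect_equal(rep2$per_feature$cv_before, rep2$per_feature$cv_after)
  # a QC with a 10x global sensitivity drop is flagged
  drop <- fsc
  ab <- abundances(drop, "log10")
  qcCols <- which(sampleInfo(drop)$sample_type == "qc")
  ab[, qcCols[1]] <- ab[, qcCols[1]] - 1  # 10x down in log10
  SummarizedExperiment::assay(drop, "log10") <- ab
  rep3 <- qcDiagnostics(drop, drop, m)
  expect_identical(rep3$qc_outliers,
                   sampleInfo(drop)$sample_id[qcCols[1]])
})

test_that("slope estimates are unbiased over seeded replicates", {
  set.seed(2024)
  qcIdx <- c(1:5, 11, 17, 23)
  trueSlope <- -0.0018
  err <- replicate(200, {
    y <- 6 + trueSlope * qcIdx + rnorm(8, 0, 0.01)
    fit <- lm.fit(cbind(1, qcIdx), y)
    fit$coefficients[2] - trueSlope
  })
  # reference distribution via the package's fit on the same draws
  set.seed(2024)
  errPkg <- replicate(200, {
    y <- 6 + trueSlope * qcIdx + rnorm(8, 0, 0.01)
    ab <- matrix(10^c(y, rep(6, 15)), 1)
    fs <- makeFset(ab, mz = 218, rt = 216,
                   groups = c(rep("QC", 8),
                              rep(c("Blank", "Low", "High"), each = 5)),
                   types = c(rep("qc", 8), rep("incubation", 15)),
                   inj = c(qcIdx, setdiff(1:23, qcIdx)))
    fitDrift(transformAbundances(fs))$slope[1] - trueSlope
  })
  expect_equal(errPkg, unname(err), tolerance = 1e-9)
  se <- sd(errPkg) / sqrt(length(errPkg))
  expect_lt(abs(mean(errPkg)), 2 * se)
})
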