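# Fold changes, Welch's t-test, the significance filter and the
# zero-replacement/log10 transformation.

test_that("signed fold change follows the negative-reciprocal convention", {
  expect_identical(signedFoldChange(100, 200), 2)
  expect_identical(signedFoldChange(200, 100), -2)
  expect_identical(signedFoldChange(5, 5), 1)
  expect_identical(signedFoldChange(0, 10), Inf)
  expect_identical(signedFoldChange(10, 0), -Inf)
  expect_true(is.na(signedFoldChange(0, 0)))
  expect_error(signedFoldChange(-1, 2), "non-negative")
})

test_that("Welch t matches the textbook formulas and stats::t.test", {
  w <- welchT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.674235, tolerance = 1e-6)
  expect_equal(w$df, 4, tolerance = 1e-9)
  expect_equal(w$p, 0.021312, tolerance = 1e-4)
  # identical samples with nonzero variance
  w0 <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_identical(w0$t, 0)
  expect_identical(w0$p, 1)
  # degenerate zero-variance cases
  expect_identical(welchT(c(1, 1), c(2, 2))$p, 0)
  expect_identical(welchT(c(1, 1), c(1, 1))$p, 1)
  expect_error(welchT(1, c(1, 2)), "at least 2")
  # 1000 random inputs against the reference implementation
  set.seed(99)
  for (i in 1:1000) {
    x <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    w <- welchT(x, y)
    tt <- t.test(x, y, var.equal = FALSE)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-8)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  }
})

# hand-built 6-feature toy table: Blank/Low/High x 5 replicates
.toyFset <- function() {
  ab <- rbind(
    c(rep(10, 5), rep(100, 5), rep(200, 5)) + rep(c(1, -1), len = 15),
    c(rep(100, 5), rep(101, 5), rep(102, 5)) + rep(c(0.5, -0.5), len = 15),
    c(rep(0, 5), rep(50, 5), rep(80, 5)) + c(rep(0, 5), rep(c(2, -2), 5)),
    c(rep(100, 5), rep(100, 5), rep(100, 5)) + rnorm(15, 0, 30),
    c(rep(400, 5), rep(100, 5), rep(90, 5)) + rep(c(3, -3), len = 15),
    c(rep(10, 5), rep(100, 5), rep(200, 5)) + rep(c(1, -1), len = 15))
  makeFset(ab, mz = c(218.1, 219.1, 232.1, 300.2, 350.3, 400.1),
           rt = c(216, 216, 343, 200, 59, 60),
           groups = rep(c("Blank", "Low", "High"), each = 5))
}

test_that("the filter matches a brute-force evaluation of its predicate", {
  set.seed(42)
  fs <- .toyFset()
  res <- applyFilters(fs)
  # independent brute force with stats::t.test and plain ratios
  ab <- abundances(fs)
  grp <- sampleInfo(fs)$group
  pairs <- list(c("Blank", "Low"), c("Blank", "High"), c("Low", "High"))
  brute <- vapply(seq_len(nrow(ab)), function(i) {
    hit <- vapply(pairs, function(pr) {
      a <- ab[i, grp == pr[1]]; b <- ab[i, grp == pr[2]]
      r <- mean(b) / mean(a)
      fc <- if (!is.finite(r)) Inf else if (r >= 1) r else -1 / r
      p <- tryCatch(t.test(a, b)$p.value, error = function(e) 1)
      abs(fc) > 1.5 && p < 0.001
    }, logical(1))
    any(hit) && featureRt(fs)[i] >= 60 && featureRt(fs)[i] <= 600
  }, logical(1))
  expect_identical(res$verdicts$passed, brute)
  # the rt window is inclusive: rt 59 removed, rt 60 kept
  expect_false(res$verdicts$passed[5])
  expect_true(res$verdicts$rt_pass[6])
  expect_true(res$verdicts$passed[6])
})

test_that("missing groups are rejected by name", {
  ab <- matrix(1:12, 2)
  fs <- makeFset(ab, mz = c(100, 200), rt = c(100, 200),
                 groups = rep(c("Low", "High"), each = 3))
  expect_error(compareGroups(fs), "Blank")
})

test_that("the filter is monotone in its thresholds", {
  set.seed(21)
  for (rep in 1:5) {
    ab <- matrix(rlnorm(20 * 15, log(100), 1), 20)
    ab[1:5, 6:15] <- ab[1:5, 6:15] * 8  # some dose-dependent rows
    fs <- makeFset(ab, mz = 100 + 1:20, rt = rep(200, 20),
                   groups = rep(c("Blank", "Low", "High"), each = 5))
    strict <- applyFilters(fs, fc_thresh = 2, p_thresh = 1e-4)
    loose <- applyFilters(fs, fc_thresh = 1.2, p_thresh = 1e-2)
    expect_true(all(strict$verdicts$passed <= loose$verdicts$passed))
  }
})

test_that("zero replacement uses the global minimum positive abundance", {
  ab <- matrix(c(0, 5, 10, 2), 1)
  fs <- makeFset(ab, mz = 100, rt = 100,
                 groups = c("Blank", "Blank", "Low", "Low"))
  out <- abundances(transformAbundances(fs), "log10")
  expect_equal(as.numeric(out), log10(c(2, 5, 10, 2)))
  # without zeros the replacement is a no-op
  ab2 <- matrix(c(1, 5, 10, 2), 1)
  fs2 <- makeFset(ab2, mz = 100, rt = 100,
                  groups = c("Blank", "Blank", "Low", "Low"))
  expect_equal(as.numeric(abundances(transformAbundances(fs2), "log10")),
               log10(c(1, 5, 10, 2)))
  # the minimum is global across features, not per row
  ab3 <- rbind(c(0, 100), c(3, 50))
  fs3 <- makeFset(ab3, mz = c(100, 200), rt = c(100, 200),
                  groups = c("Blank", "High"))
  out3 <- abundances(transformAbundances(fs3), "log10")
  expect_equal(out3[1, 1], log10(3))
  # all-zero tables are rejected
  fs4 <- makeFset(matrix(0, 1, 2), mz = 100, rt = 100,
                  groups = c("Blank", "High"))
  expect_error(transformAbundances(fs4), "zero")
})
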