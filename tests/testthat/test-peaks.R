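# ROI extraction, peak detection, cross-sample grouping and gap filling.

test_that("ROI building separates species by m/z tolerance", {
  mkRun <- function(mzs, nScans = 50, sigma_ppm = 0, seed = 1) {
    set.seed(seed)
    cc <- do.call(rbind, lapply(mzs, function(m) {
      data.frame(scan = seq_len(nScans), rt = (seq_len(nScans) - 1) * 0.5,
                 mz = m * (1 + rnorm(nScans, 0, sigma_ppm) * 1e-6),
                 intensity = 1000)
    }))
    SpectrumRun(cc)
  }
  # one species, jitter below tolerance -> one ROI
  expect_length(extractRois(mkRun(218.1539, sigma_ppm = 1), ppm_tol = 10), 1)
  # two species 50 ppm apart at 5 ppm tolerance -> two ROIs
  rois <- extractRois(mkRun(c(218.1539, 218.1539 * (1 + 50e-6))),
                      ppm_tol = 5)
  expect_length(rois, 2)
  # ROI mean m/z close to truth (standard error of the mean at 1 ppm, n=50)
  roi <- extractRois(mkRun(218.1539, sigma_ppm = 1, seed = 7),
                     ppm_tol = 10)[[1]]
  expect_lt(abs(ppmError(roi$mz, 218.1539)), 2)
  # short traces are discarded
  expect_length(extractRois(mkRun(218.1539, nScans = 3), min_scans = 5), 0)
  # empty run -> empty list
  expect_length(extractRois(SpectrumRun(data.frame(
    scan = integer(), rt = numeric(), mz = numeric(),
    intensity = numeric()))), 0)
})

test_that("peak detection recovers a clean Gaussian and splits doublets", {
  eic <- makeGaussianEIC(apex = 100, sigma = 4, area = 1e6)
  pk <- detectPeaks(eic, interval = 0.5)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$rt - 100), 0.5 + 1e-9)     # within one scan
  expect_equal(pk$area, 1e6, tolerance = 0.05) # trapezoid vs true area
  # flat zero trace
  flat <- structure(list(mz = 100, points = data.frame(
    scan = 1:50, rt = (1:50) / 2, mz = 100, intensity = 0)), class = "EIC")
  expect_identical(nrow(detectPeaks(flat, interval = 0.5)), 0L)
  # two Gaussians 6 sigma apart -> resolved into two peaks
  e1 <- makeGaussianEIC(apex = 100, sigma = 4, area = 1e6,
                        rt_range = c(60, 180))
  e2 <- makeGaussianEIC(apex = 124, sigma = 4, area = 8e5,
                        rt_range = c(60, 180))
  pts <- rbind(e1$points, e2$points)
  pts <- aggregate(intensity ~ scan + rt + mz, pts, sum)
  dbl <- structure(list(mz = 218.1539, points = pts[order(pts$scan), ]),
                   class = "EIC")
  expect_identical(nrow(detectPeaks(dbl, interval = 0.5)), 2L)
  expect_error(detectPeaks(eic, width_bounds = c(5, 2)), "width_bounds")
})

test_that("grouping merges replicates and splits by retention time", {
  mkPeaks <- function(n, mz, rt, area = 1e5) {
    data.frame(sample_id = paste0("S", seq_len(n)), mz = mz, rt = rt,
               rt_lo = rt - 10, rt_hi = rt + 10, area = area, snr = 50,
               apex_intensity = area / 10)
  }
  sd20 <- data.frame(sample_id = paste0("S", 1:20), group = "High",
                     sample_type = "incubation", injection_index = 1:20,
                     polarity = "pos")
  # identical species in 20 runs -> one feature with 20 abundances
  fs <- groupFeatures(mkPeaks(20, 218.1539, 216), sd20)
  expect_identical(nrow(fs), 1L)
  expect_true(all(abundances(fs) > 0))
  # same m/z, 300 s apart -> two features
  pk2 <- rbind(mkPeaks(5, 218.1539, 100), mkPeaks(5, 218.1539, 400))
  sd5 <- sd20[1:5, ]
  fs2 <- groupFeatures(pk2, sd5, rt_tol = 10)
  expect_identical(nrow(fs2), 2L)
  # hydroxy-metabolite isomer pair 47 s apart (as on a HILIC separation)
  pk3 <- rbind(mkPeaks(5, 276.1954, 269), mkPeaks(5, 276.1954, 316))
  expect_identical(nrow(groupFeatures(pk3, sd5, rt_tol = 10)), 2L)
  # duplicate peaks of one sample resolve to the larger area
  dup <- rbind(mkPeaks(1, 218.1539, 216, area = 100),
               mkPeaks(1, 218.1539, 217, area = 900))
  fs3 <- groupFeatures(dup, sd5[1, ])
  expect_identical(as.numeric(abundances(fs3)[1, 1]), 900)
  # feature inventory invariant to input row order
  pkAll <- rbind(pk2, pk3)
  fsA <- groupFeatures(pkAll, sd5)
  fsB <- groupFeatures(pkAll[rev(seq_len(nrow(pkAll))), ], sd5)
  expect_identical(rownames(fsA), rownames(fsB))
  expect_identical(abundances(fsA), abundances(fsB))
})

test_that("gap filling reintegrates the consensus window", {
  sc <- noiseFreeScenario(list(
    compoundSpec("solo", "C14H19NO", rt_apex = 200, base_abundance = 1e6,
                 dose_response = c(Blank = 0, Low = 1, High = 1),
                 class = "parent", origin = "substrate")))
  runHigh <- simulateRun(sc$species, "High", "incubation", 1, sc,
                         sampleId = "S1", seed = 1)$run
  runBlank <- simulateRun(sc$species, "Blank", "incubation", 2, sc,
                          sampleId = "S2", seed = 2)$run
  peaks <- detectPeaksRun(runHigh, interval = 1)
  mono <- peaks[which.max(peaks$area), , drop = FALSE]
  sd <- data.frame(sample_id = c("S1", "S2"), group = c("High", "Blank"),
                   sample_type = "incubation", injection_index = 1:2,
                   polarity = "pos")
  fs <- groupFeatures(mono, sd)
  fs <- fillMissing(fs, list(S1 = runHigh, S2 = runBlank), interval = 1)
  # noise off: the filled Blank abundance is exactly zero
  expect_identical(as.numeric(abundances(fs)[1, "S2"]), 0)
  expect_true(isFilled(fs)[1, "S2"])
  # noise on: filling integrates noise > 0 (chemical bleed in the window)
  scN <- sc; scN$noise$bleed_area <- 200
  runBlankN <- simulateRun(scN$species, "Blank", "incubation", 2, scN,
                           sampleId = "S2", seed = 3)$run
  fsN <- groupFeatures(mono, sd)
  fsN <- fillMissing(fsN, list(S1 = runHigh, S2 = runBlankN), interval = 1)
  expect_gt(abundances(fsN)[1, "S2"], 0)
  # filling a sample where the species is present recovers the detected
  # area (same integral over the same window)
  fs2 <- groupFeatures(mono, sd[1, , drop = FALSE])
  detected <- abundances(fs2)[1, 1]
  ab <- abundances(fs2); ab[1, 1] <- 0
  SummarizedExperiment::assay(fs2, "abundance") <- ab
  fs2 <- fillMissing(fs2, list(S1 = runHigh), interval = 1)
  expect_equal(as.numeric(abundances(fs2)[1, 1]), as.numeric(detected),
               tolerance = 0.05)
})
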