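# The ground-truth simulator: planted areas, isotopologue ratios, design
# sequence and seed contracts.

test_that("noise-free planted species integrates to its planted area", {
  sc <- noiseFreeScenario(list(
    compoundSpec("solo", "C14H19NO", rt_apex = 200, base_abundance = 1e6,
                 dose_response = c(Blank = 0, Low = 1, High = 2),
                 class = "parent", origin = "substrate")))
  res <- simulateRun(sc$species, group = "High", sampleType = "incubation",
                     injectionIndex = 1, scenario = sc, seed = 1)
  cc <- centroids(res$run)
  mono <- cc[abs(ppmError(cc$mz, ionMz(monoisotopicMass("C14H19NO"),
                                       "[M+H]+"))) < 1, ]
  area <- sum(diff(mono$rt) * (head(mono$intensity, -1) +
                                 mono$intensity[-1]) / 2)
  expect_equal(area, 2e6, tolerance = 0.01)  # quadrature error only
  expect_equal(res$ledger$dose_abundance[1], 2e6)
})

test_that("substrate-derived species are absent from Blank-group runs", {
  sc <- noiseFreeScenario(list(
    compoundSpec("solo", "C14H19NO", rt_apex = 200, base_abundance = 1e6,
                 dose_response = c(Blank = 0, Low = 1, High = 2),
                 class = "parent", origin = "substrate")))
  res <- simulateRun(sc$species, group = "Blank",
                     sampleType = "incubation", injectionIndex = 1,
                     scenario = sc, seed = 1)
  expect_identical(nrow(centroids(res$run)), 0L)
  expect_null(res$ledger)
})

test_that("planted M+1/M ratio follows the carbon count", {
  sc <- noiseFreeScenario(list(
    compoundSpec("solo", "C14H19NO", rt_apex = 200, base_abundance = 1e6,
                 dose_response = c(Blank = 0, Low = 1, High = 1),
                 class = "parent", origin = "substrate")))
  res <- simulateRun(sc$species, group = "High", sampleType = "incubation",
                     injectionIndex = 1, scenario = sc, seed = 1)
  cc <- centroids(res$run)
  mono <- abs(ppmError(cc$mz, 218.153941)) < 1
  m1 <- abs(ppmError(cc$mz, 218.153941 + c13Spacing())) < 1
  ratio <- sum(cc$intensity[m1]) / sum(cc$intensity[mono])
  expect_equal(ratio, 14 * 0.0107, tolerance = 1e-3)  # 0.1498
})

test_that("rejections: empty grid, too few replicates", {
  sc <- noiseFreeScenario()
  sc$grid <- list(rt_min = 10, rt_max = 0, interval = 0.5)
  expect_error(simulateRun(sc$species, "High", "incubation", 1, sc),
               "grid")
  sc2 <- smallScenario()
  sc2$design$replicates <- 1L
  expect_error(simulateStudy(sc2), "replicates")
})

test_that("the injection sequence places QCs as designed", {
  set.seed(1)
  des <- designSequence(list(replicates = 5L, qc_lead_in = 5L,
                             qc_every = 5L, n_substrate_blank = 2L,
                             n_enzyme_blank = 2L))
  expect_identical(sum(des$sample_type == "qc"), 8L)  # 5 lead-in + 3
  expect_identical(sum(des$sample_type == "incubation"), 15L)
  expect_identical(des$injection_index, seq_len(nrow(des)))
  # lead-in block is all QC
  expect_true(all(des$sample_type[1:5] == "qc"))
  # one QC after every 5th incubation sample
  incPos <- which(des$sample_type == "incubation")
  expect_true(all(des$sample_type[incPos[c(5, 10, 15)] + 1] == "qc"))
})

test_that("seeds control injection order but not the species inventory", {
  sc <- smallScenario()
  s1 <- simulateStudy(sc, seed = 1)
  s2 <- simulateStudy(sc, seed = 2)
  s1b <- simulateStudy(sc, seed = 1)
  expect_false(identical(s1$design$sample_id, s2$design$sample_id))
  expect_identical(vapply(s1$species, `[[`, character(1), "name"),
                   vapply(s2$species, `[[`, character(1), "name"))
  expect_identical(s1$design, s1b$design)
  expect_identical(centroids(s1$runs[[3]]), centroids(s1b$runs[[3]]))
})

test_that("QC composition is the mean of the incubation compositions", {
  sc <- noiseFreeScenario()
  sc$drift_rate <- 0
  led <- list()
  for (g in c("Blank", "Low", "High"))
    led[[g]] <- simulateRun(sc$species, g, "incubation", 1, sc,
                            sampleId = g)$ledger
  qc <- simulateRun(sc$species, "QC", "qc", 1, sc, sampleId = "QC")$ledger
  for (i in seq_len(nrow(qc))) {
    sp <- qc$species[i]; ad <- qc$adduct[i]
    incAb <- vapply(c("Blank", "Low", "High"), function(g) {
      df <- led[[g]]  # NULL when the group plants nothing
      if (is.null(df)) return(0)
      hit <- df$species == sp & df$adduct == ad
      if (!any(hit)) 0 else df$dose_abundance[hit]
    }, numeric(1))
    expect_equal(qc$dose_abundance[i], mean(incAb), tolerance = 1e-9)
  }
})

test_that("blank runs contain the right species classes", {
  sc <- noiseFreeScenario()
  sc$species <- defaultScenario()$species
  enz <- simulateRun(sc$species, "Blank", "enzyme_blank", 1, sc)$ledger
  sub <- simulateRun(sc$species, "Blank", "substrate_blank", 1, sc)$ledger
  # enzyme blank: drug without enzymes -> parent, artifact and impurity but
  # no enzymatically formed metabolites
  expect_true(all(c("parent", "powder-impurity-dehydro",
                    "parent-dehydro-artifact") %in% enz$species))
  expect_false(any(grepl("^M-", enz$species)))
  # substrate blank: enzymes without drug -> none of the substrate species
  expect_null(sub)
})

test_that("ledger species counts survive a serialization round-trip", {
  sc <- smallScenario()
  st <- simulateStudy(sc, seed = 3)
  tmp <- tempfile(fileext = ".csv")
  write.csv(st$ledger, tmp, row.names = FALSE)
  back <- read.csv(tmp)
  expect_identical(nrow(back), nrow(st$ledger))
  expect_equal(table(back$class), table(st$ledger$class))
})
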