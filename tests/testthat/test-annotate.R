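# Isotope/adduct/shift matching, origin classification and isomer linking.

test_that("co-eluting 13C pairs are linked as isotopes", {
  # protonated parent and its M+1, co-eluting at 216 s
  ab <- rbind(rep(1e6, 4), rep(1.5e5, 4))
  fs <- makeFset(ab, mz = c(218.1540, 219.1572), rt = c(216, 216),
                 groups = c("Blank", "Low", "High", "High"))
  iso <- annotateIsotopes(fs)
  expect_identical(nrow(iso), 1L)
  expect_identical(iso$k, 1L)
  expect_identical(iso$anchor, "M218T216")
  # spacing error below 5 ppm of the expected isotopologue position
  expect_lt(abs(iso$ppm), 5)
  # same m/z pair 120 s apart: no link (co-elution required)
  fs2 <- makeFset(ab, mz = c(218.1540, 219.1572), rt = c(216, 336),
                  groups = c("Blank", "Low", "High", "High"))
  expect_identical(nrow(annotateIsotopes(fs2)), 0L)
  # adduct isotopologue triplet at +1.00336 and +2.00671
  ab3 <- rbind(rep(1e6, 4), rep(3e5, 4), rep(5e4, 4))
  fs3 <- makeFset(ab3, mz = c(471.2771, 472.2805, 473.2838),
                  rt = c(350, 350, 350),
                  groups = c("Blank", "Low", "High", "High"))
  iso3 <- annotateIsotopes(fs3)
  expect_identical(sort(iso3$k), c(1L, 2L))
  expect_true(all(iso3$anchor == "M471T350"))
})

test_that("mass-shift matching identifies adducts and transformations", {
  ms <- matchMassShifts(c(471.2771, 232.1331, 150.0000), "C14H19NO")
  expect_identical(ms$type[1], "adduct")
  expect_identical(ms$rule[1], "[2M+2H+Cl]+")
  expect_lt(abs(ms$ppm[1]), 5)
  expect_identical(ms$type[2], "transformation")
  expect_identical(ms$rule[2], "oxo-")
  expect_lt(abs(ms$ppm[2]), 5)
  expect_true(is.na(ms$type[3]))  # nothing within tolerance
  # HO- and dihydro-oxo- share the same net +O shift: flagged ambiguous
  ms2 <- matchMassShifts(234.1488, "C14H19NO")
  expect_true(ms2$ambiguous)
  expect_true(grepl("HO-", ms2$rule) && grepl("dihydro-oxo-", ms2$rule))
})

test_that("the origin ladder orders artifact, impurity, contaminant, metabolite", {
  # dehydro-shift at the parent's rt, absent in blanks -> in-source artifact
  expect_identical(classifyOrigin(TRUE, TRUE, FALSE, FALSE, TRUE),
                   "artifact")
  # dehydro-shift elsewhere, present in the enzyme blank only -> impurity
  expect_identical(classifyOrigin(TRUE, FALSE, TRUE, FALSE, TRUE),
                   "impurity")
  # dihydro-shift, dose-responsive, absent in both blanks -> metabolite
  expect_identical(classifyOrigin(FALSE, TRUE, FALSE, FALSE, TRUE),
                   "metabolite")
  # present in the substrate blank -> background contaminant
  expect_identical(classifyOrigin(FALSE, FALSE, TRUE, TRUE, TRUE),
                   "background")
  # blanks missing -> undetermined, never guessed
  expect_identical(classifyOrigin(FALSE, FALSE, NA, NA, TRUE),
                   "undetermined")
})

test_that("isomers are numbered by ascending retention time", {
  ann <- data.frame(feature = c("a", "b"), rt = c(316, 269),
                    class = "metabolite", rule = "HO-")
  out <- annotateIsomers(ann)
  expect_identical(out$isomer_number, c(2L, 1L))
  # single match: no link
  out1 <- annotateIsomers(ann[1, ])
  expect_true(is.na(out1$isomer_number))
  # three matches -> 1..3 by rt
  ann3 <- data.frame(feature = c("a", "b", "c"), rt = c(316, 90, 269),
                     class = "metabolite", rule = "HO-")
  expect_identical(annotateIsomers(ann3)$isomer_number, c(3L, 1L, 2L))
})

# full annotation cascade on a constructed significant-feature table that
# mirrors the planted default scenario (parent + isotope + artifact +
# impurity + metabolite + adduct, with blank evidence columns)
.annFset <- function(shuffle = FALSE) {
  pbp <- ionMz(monoisotopicMass("C14H19NO"), "[M+H]+")
  mz <- c(pbp, pbp + c13Spacing(), pbp - 2.015650, pbp - 2.015650,
          pbp + 2.015650, ionMz(monoisotopicMass("C14H19NO"),
                                "[2M+2H+Cl]+"))
  rt <- c(216, 216, 216, 114, 226, 216)
  base <- c(1e7, 1.5e6, 3e5, 2e5, 1.2e6, 4e4)
  groups <- c(rep("Blank", 3), rep("Low", 3), rep("High", 3),
              rep("QC", 3), "Blank", "Blank")
  types <- c(rep("incubation", 9), rep("qc", 3), "enzyme_blank",
             "substrate_blank")
  mult <- c(rep(0.001, 3), rep(1, 3), rep(2, 3), rep(1, 3), 2, 0.001)
  ab <- outer(base, mult)
  ab <- ab * matrix(exp(rnorm(length(ab), 0, 0.02)), nrow(ab))
  # metabolite (row 5) needs enzymes: absent in the enzyme blank
  ab[5, 13] <- 120
  idx <- if (shuffle) c(4, 6, 1, 5, 3, 2) else 1:6
  makeFset(ab[idx, ], mz = mz[idx], rt = rt[idx], groups = groups,
           types = types, inj = seq_along(groups))
}

test_that("the annotation cascade classifies a constructed study correctly", {
  set.seed(77)
  fs <- .annFset()
  ann <- annotateFeatures(fs, "C14H19NO", noise_area = 100)
  byName <- setNames(ann$class, ann$feature)
  expect_identical(unname(byName["M218T216"]), "parent")
  expect_identical(unname(byName["M219T216"]), "isotope")
  expect_identical(unname(byName["M216T216"]), "artifact")
  expect_identical(unname(byName["M216T114"]), "impurity")
  expect_identical(unname(byName["M220T226"]), "metabolite")
  expect_identical(unname(byName["M471T216"]), "adduct")
  # every mass-based annotation's recomputed ppm error is within tolerance
  expect_true(all(abs(ann$ppm_error) <= 5, na.rm = TRUE))
  # annotation is independent of feature order
  set.seed(77)
  fs2 <- .annFset(shuffle = TRUE)
  ann2 <- annotateFeatures(fs2, "C14H19NO", noise_area = 100)
  byName2 <- setNames(ann2$class, ann2$feature)
  expect_identical(byName2[names(byName)], byName)
  # ... and idempotent in the sense of being a pure function
  ann3 <- annotateFeatures(fs, "C14H19NO", noise_area = 100)
  expect_identical(ann, ann3)
})
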