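test_that("cohort specs validate their invariants", {
  expect_error(cohortSpec(nPerGroup = 1, seed = 1), "nPerGroup")
  expect_error(cohortSpec(dispersion = 0, seed = 1), "dispersion")
  expect_error(cohortSpec(seed = 1,
    plantedGenera = data.frame(genus = "g999", direction = "up",
                               fold = 2), nGenera = 10), "genus set")
  expect_error(cohortSpec(seed = 1,
    plantedGenera = data.frame(genus = "g001", direction = "up",
                               fold = -2), nGenera = 10), "fold")
  expect_error(cohortSpec(nPerGroup = 5), "seed")
})

test_that("generation is seed-deterministic and well-formed", {
  spec <- cohortSpec(nPerGroup = 5, nGenera = 12, seed = 77)
  g1 <- generateCohort(spec)
  g2 <- generateCohort(spec)
  expect_identical(abundances(g1$table), abundances(g2$table))
  a <- abundances(g1$table)
  expect_true(all(a >= 0 & a == round(a)))
  expect_false(anyNA(a))
  # totals concentrate around the requested depth
  expect_true(all(abs(colSums(a) - spec$readDepth) <
                    6 * sqrt(spec$readDepth)))
  # metadata covers both groups with pairing ids
  md <- sampleData(g1$table)
  expect_equal(sum(md$group == "MS"), 5)
  expect_equal(sum(md$group == "HV"), 5)
})

test_that("planted fold effects are realized up to closure attenuation", {
  # Monte-Carlo oracle: the across-seed mean case/control ratio of the
  # planted genus approaches the planted fold (attenuated by closure)
  planted <- data.frame(genus = "g020", direction = "up", fold = 4)
  ratios <- vapply(1:60, function(s) {
    spec <- cohortSpec(nPerGroup = 8, nGenera = 25,
                       plantedGenera = planted, dispersion = 300,
                       readDepth = 2e4, seed = 9000 + s)
    rel <- toRelative(generateCohort(spec)$table)
    md <- sampleData(rel)
    a <- abundances(rel)["g020", ]
    mean(a[md$group == "MS"]) / mean(a[md$group == "HV"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4) / 4, 0.2)
})

test_that("a null spec produces no systematic group differences", {
  spec <- cohortSpec(nPerGroup = 15, nGenera = 10, dispersion = 100,
                     seed = 123)
  rel <- toRelative(generateCohort(spec)$table)
  da <- diffAbundance(rel, case = "MS", control = "HV", nPerm = 50,
                      seed = 4)
  # no genus should show overwhelming evidence under the null
  expect_gt(min(da$p), 1e-4)
})

test_that("impossible fold effects are rejected", {
  spec <- cohortSpec(nPerGroup = 3, nGenera = 5, seed = 2,
                     plantedGenera = data.frame(
                       genus = "g001", direction = "up", fold = 1e6))
  expect_error(generateCohort(spec), "above 1")
})

test_that("paired cohorts control shared-genus structure", {
  mkSpec <- function(seed) cohortSpec(nPerGroup = 8, nGenera = 20,
                                      dispersion = 150, readDepth = 1e4,
                                      seed = seed)
  # full sharing: per-individual shared percentage is essentially 100
  spec1 <- pairedCohortSpec(mkSpec(3), mkSpec(4),
                            sharedGenusFraction = c(HV = 1, MS = 1))
  pc1 <- generatePairedCohort(spec1)
  res1 <- sharedGenusAnalysis(pc1$oral, pc1$faecal)
  expect_gt(mean(c(res1$HV$sharedPercent, res1$MS$sharedPercent)), 85)

  # no sharing: pooled shared counts collapse
  spec0 <- pairedCohortSpec(mkSpec(5), mkSpec(6),
                            sharedGenusFraction = c(HV = 0, MS = 0))
  pc0 <- generatePairedCohort(spec0)
  res0 <- sharedGenusAnalysis(pc0$oral, pc0$faecal)
  expect_equal(unname(res0$HV$venn["shared"]), 0)
  expect_equal(unname(res0$MS$venn["shared"]), 0)

  # an intermediate target is matched approximately at the pooled level
  spec5 <- pairedCohortSpec(mkSpec(7), mkSpec(8),
                            sharedGenusFraction = c(HV = 0.3, MS = 0.3))
  pc5 <- generatePairedCohort(spec5)
  res5 <- sharedGenusAnalysis(pc5$oral, pc5$faecal)
  sharedFrac <- res5$HV$venn["shared"] / sum(res5$HV$venn)
  expect_lt(abs(sharedFrac - 0.3), 0.12)
})

test_that("requested cross-compartment correlations carry their sign", {
  cc <- data.frame(oralGenus = "g003", faecalGenus = "g007",
                   sign = 1)
  hits <- 0
  nSeeds <- 25
  for (s in seq_len(nSeeds)) {
    spec <- pairedCohortSpec(
      cohortSpec(nPerGroup = 20, nGenera = 12, dispersion = 150,
                 readDepth = 1e4, seed = 5000 + s),
      cohortSpec(nPerGroup = 20, nGenera = 12, dispersion = 150,
                 readDepth = 1e4, seed = 6000 + s),
      sharedGenusFraction = c(HV = 0.5, MS = 0.5),
      crossCorrelation = cc)
    pc <- generatePairedCohort(spec)
    res <- crossCompartmentCorrelation(pc$oral, pc$faecal)
    if (res$rho["g003", "g007"] > 0) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.95 * nSeeds))

  expect_error(pairedCohortSpec(
    cohortSpec(nPerGroup = 4, nGenera = 5, seed = 1),
    cohortSpec(nPerGroup = 4, nGenera = 5, seed = 2),
    sharedGenusFraction = c(HV = 0.5, MS = 0.5),
    crossCorrelation = data.frame(oralGenus = "g099",
                                  faecalGenus = "g001", sign = 1)),
    "absent oral genus")
})

test_that("validation cohorts keep the signal and add only a batch tilt", {
  planted <- data.frame(genus = c("g005", "g008"),
                        direction = c("up", "down"), fold = c(3, 3))
  train <- generateCohort(cohortSpec(nPerGroup = 10, nGenera = 15,
                                     plantedGenera = planted,
                                     dispersion = 150, seed = 21))
  vspec <- cohortSpec(nPerGroup = 10, nGenera = 15, dispersion = 150,
                      seed = 22)
  v0a <- generateValidationCohort(vspec, train$truth, shift = 0)
  v0b <- generateValidationCohort(vspec, train$truth, shift = 0)
  expect_identical(abundances(v0a$table), abundances(v0b$table))
  expect_identical(v0a$truth$plantedGenera, planted)
  expect_equal(unique(sampleData(v0a$table)$cohort), "validation")

  # the planted direction survives in the shifted cohort
  v2 <- generateValidationCohort(vspec, train$truth, shift = 1)
  rel <- toRelative(v2$table)
  md <- sampleData(rel)
  a <- abundances(rel)
  expect_gt(mean(a["g005", md$group == "MS"]),
            mean(a["g005", md$group == "HV"]))
})
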