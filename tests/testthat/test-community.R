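test_that("taxon selection applies the strict 1% rule", {
  m <- matrix(c(0.012, 0.98, 0.008,
                0.010, 0.98, 0.010), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  tab <- abundanceTable(sweep(m, 2, colSums(m), "/"), normalized = FALSE)
  tab <- toRelative(abundanceTable(m * 1000))
  sel <- selectTaxa(tab)
  expect_true("gA" %in% sel)     # 1.2% in one sample suffices
  expect_true("gB" %in% sel)
  expect_false("gC" %in% sel)    # never strictly above 1%

  set.seed(6)
  big <- toRelative(abundanceTable(
    matrix(rpois(300, 20), 30, 10,
           dimnames = list(sprintf("g%02d", 1:30),
                           sprintf("s%02d", 1:10)))))
  a <- abundances(big)
  oracle <- rownames(a)[apply(a, 1, max) > 0.01]
  expect_setequal(selectTaxa(big), oracle)

  expect_error(selectTaxa(abundanceTable(
    matrix(5, 1, 1, dimnames = list("g", "s")))), "normalized")
})

test_that("identity merge reproduces the solo model", {
  lib <- makeTestLibrary(3, seed = 5)
  solo <- lib[[2]]
  cm <- buildCommunityModel(list(solo), setNames(1, taxonId(solo)))
  expect_equal(coverage(cm), 1)
  expect_equal(unname(memberWeights(cm)), 1)
  expect_equal(objectiveValue(fba(cm)), objectiveValue(fba(solo)),
               tolerance = 1e-9)
  # signature boundary flux survives the merge unchanged
  sm <- attr(lib, "signatureMap")
  bfSolo <- boundaryFluxes(fba(solo), solo)
  bfComm <- boundaryFluxes(fba(cm), cm)
  met <- sm$metabolite[sm$taxon == taxonId(solo)]
  expect_equal(bfComm[[met]], bfSolo[[met]], tolerance = 1e-9)
})

test_that("non-interacting taxa combine additively by weight", {
  lib <- makeTestLibrary(4, seed = 8,
                         modes = c("secrete", "consume", "secrete",
                                   "consume"))
  sm <- attr(lib, "signatureMap")
  w <- c(0.6, 0.4)
  cm <- buildCommunityModel(lib[1:2], setNames(w, names(lib)[1:2]))
  bf <- boundaryFluxes(fba(cm), cm)
  for (k in 1:2) {
    soloBf <- boundaryFluxes(fba(lib[[k]]), lib[[k]])
    met <- sm$metabolite[k]
    expect_equal(bf[[met]], w[k] * soloBf[[met]], tolerance = 1e-6)
  }
})

test_that("weight renormalization leaves the community unchanged", {
  lib <- makeTestLibrary(3, seed = 5)
  w <- c(0.5, 0.3, 0.2)
  cm1 <- buildCommunityModel(lib, setNames(w, names(lib)))
  cm2 <- buildCommunityModel(lib, setNames(7 * w, names(lib)))
  expect_equal(memberWeights(cm1), memberWeights(cm2))
  expect_identical(fluxes(fba(cm1)), fluxes(fba(cm2)))
  # coverage reflects the unrenormalized total (capped at 1)
  cm3 <- buildCommunityModel(lib, setNames(w * 0.85, names(lib)))
  expect_equal(coverage(cm3), 0.85)
  expect_equal(memberWeights(cm3), memberWeights(cm1))
})

test_that("community construction validates its inputs", {
  lib <- makeTestLibrary(2, seed = 5)
  expect_error(buildCommunityModel(lib[c(1, 1)],
                                   setNames(c(0.5, 0.5), names(lib)[c(1, 1)])),
               "duplicate")
  expect_error(buildCommunityModel(lib, setNames(c(0, 0), names(lib))),
               "zero total")
  expect_error(buildCommunityModel(lib, setNames(0.5, names(lib)[1])),
               "missing")
})

test_that("cohort fluxes are per-sample independent with honest coverage", {
  lib <- makeTestLibrary(5, seed = 9)
  set.seed(17)
  counts <- matrix(rpois(48, 200), 8, 6,
                   dimnames = list(sprintf("g%03d", 1:8),
                                   sprintf("s%02d", 1:6)))
  md <- data.frame(sample_id = colnames(counts),
                   group = rep(c("HV", "MS"), 3))
  tab <- toRelative(abundanceTable(counts, sampleData = md))
  cf <- cohortFluxes(tab, lib, coverageFloor = 0.9)
  a <- abundances(tab)
  modelled <- intersect(selectTaxa(tab), names(lib))
  # coverage is the modelled fraction of each sample
  expect_equal(unname(cf$coverage),
               unname(colSums(a[modelled, , drop = FALSE])),
               tolerance = 1e-12)
  expect_true(all(cf$flagged == (cf$coverage < 0.9)))
  # rebuilding one sample directly gives the same profile (no leakage)
  i <- 3
  ab <- a[, i]
  present <- modelled[ab[modelled] > 0]
  cm <- buildCommunityModel(lib[present], ab[present])
  bf <- boundaryFluxes(fba(cm), cm)
  expect_equal(cf$fluxes[i, names(bf)], bf, tolerance = 1e-12)
})
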