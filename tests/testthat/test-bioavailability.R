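test_that("identical groups give null fold changes and large p", {
  set.seed(10)
  base <- matrix(rnorm(10 * 4, mean = 3), 10, 4,
                 dimnames = list(sprintf("s%02d", 1:10),
                                 sprintf("m%02d_e", 1:4)))
  X <- rbind(base, base)
  rownames(X) <- sprintf("s%02d", 1:20)
  groups <- rep(c("HV", "MS"), each = 10)
  res <- bioavailability(X, groups, case = "MS", control = "HV",
                         nPerm = 50, seed = 1)
  expect_equal(res$log2FC, rep(0, 4), tolerance = 1e-12)
  expect_false(any(res$switch))
  expect_true(all(res$p > 0.9))
  expect_false(any(res$significant))
})

test_that("the switch flag marks production/consumption reversals", {
  X <- rbind(matrix(2, 5, 2), matrix(-3, 5, 2))
  X[, 2] <- abs(X[, 2])  # second metabolite never switches
  dimnames(X) <- list(sprintf("s%d", 1:10), c("mA", "mB"))
  res <- bioavailability(X, rep(c("HV", "MS"), each = 5),
                         case = "MS", control = "HV", nPerm = 20, seed = 2)
  expect_true(res$switch[res$metabolite == "mA"])
  expect_false(res$switch[res$metabolite == "mB"])
  # fold change is computed on magnitudes: case |-3| vs control |2|
  expect_equal(res$log2FC[res$metabolite == "mA"],
               log2((3 + 1e-6) / (2 + 1e-6)), tolerance = 1e-9)
})

test_that("significance requires both p < 0.05 and q < 0.1", {
  set.seed(33)
  n <- 20
  X <- cbind(strong = c(rnorm(n / 2, 0, 0.2), rnorm(n / 2, 5, 0.2)),
             matrix(rnorm(n * 6, 1, 1), n, 6))
  colnames(X) <- c("strong", sprintf("noise%d", 1:6))
  rownames(X) <- sprintf("s%d", 1:n)
  res <- bioavailability(X, rep(c("HV", "MS"), each = n / 2),
                         case = "MS", control = "HV", nPerm = 200, seed = 5)
  srow <- res[res$metabolite == "strong", ]
  expect_lt(srow$p, 0.05)
  expect_lt(srow$q, 0.1)
  expect_true(srow$significant)
  expect_identical(res$significant, res$p < 0.05 & res$q < 0.1)
})

test_that("median summary is available and recorded honestly", {
  X <- matrix(c(1, 1, 1, 10, 2, 2, 2, 2), 4, 2,
              dimnames = list(sprintf("s%d", 1:4), c("mA", "mB")))
  res <- bioavailability(X, c("HV", "HV", "MS", "MS"), case = "MS",
                         control = "HV", nPerm = 10, seed = 1,
                         summary = "median")
  expect_equal(res$summaryCase[res$metabolite == "mA"], median(c(1, 10)))
})

test_that("truth linkage derives expected directions from signatures", {
  lib <- makeTestLibrary(4, seed = 12,
                         modes = c("secrete", "consume", "secrete",
                                   "secrete"))
  planted <- data.frame(genus = c("g001", "g002", "g003"),
                        direction = c("up", "up", "down"),
                        fold = c(2, 2, 2))
  truth <- structure(list(plantedGenera = planted, groups = c("HV", "MS"),
                          caseGroup = "MS"), class = "syntheticTruth")
  linked <- linkTruthToLibrary(truth, lib)
  eb <- linked$expectedBioavailability
  sm <- attr(lib, "signatureMap")
  # g001 up & secretes m01 -> more secretion (positive shift)
  expect_equal(eb$expectedSign[eb$metabolite == sm$metabolite[1]], 1)
  # g002 up & consumes m02 -> more consumption (negative shift)
  expect_equal(eb$expectedSign[eb$metabolite == sm$metabolite[2]], -1)
  # g003 down & secretes m03 -> less secretion (negative shift)
  expect_equal(eb$expectedSign[eb$metabolite == sm$metabolite[3]], -1)
  # untouched taxon's metabolite is not listed
  expect_false(sm$metabolite[4] %in% eb$metabolite)
})
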