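mkPairedTables <- function(oralMat, faecalMat, groups) {
  # matrices: subjects x genera; same subjects in both compartments
  nSub <- nrow(oralMat)
  subj <- sprintf("sub%02d", seq_len(nSub))
  mk <- function(M, comp) {
    m <- t(M)
    dimnames(m) <- list(colnames(M), paste0(subj, "_", comp))
    md <- data.frame(sample_id = colnames(m), subject_id = subj,
                     group = groups, compartment = comp)
    abundanceTable(m, sampleData = md)
  }
  list(oral = mk(oralMat, "oral"), faecal = mk(faecalMat, "faecal"))
}

test_that("cross-compartment Spearman recovers exact rank relations", {
  set.seed(14)
  base <- matrix(rexp(11 * 3), 11, 3,
                 dimnames = list(NULL, c("gA", "gB", "gC")))
  faecal <- base
  faecal[, "gB"] <- max(base[, "gB"]) + 1 - base[, "gB"]  # reversed ranks
  tabs <- mkPairedTables(base, faecal, rep("HV", 11))
  res <- crossCompartmentCorrelation(tabs$oral, tabs$faecal)
  expect_equal(res$rho["gA", "gA"], 1)
  expect_equal(res$rho["gB", "gB"], -1)
  expect_equal(res$n, 11)

  # full matrix equals Pearson on ranks (brute-force oracle)
  oracle <- cor(apply(base, 2, rank), apply(faecal, 2, rank))
  expect_equal(unname(res$rho), unname(oracle), tolerance = 1e-12)

  expect_error(crossCompartmentCorrelation(
    tabs$oral[, 1:2], tabs$faecal[, 1:2]), "3 paired")
})

test_that("shared-genus Venn counts match manual enumeration", {
  # 3 subjects, hand-built presence patterns
  oral <- rbind(c(1, 1, 0, 0, 2),
                c(1, 0, 1, 0, 0),
                c(0, 1, 0, 0, 1))
  faecal <- rbind(c(0, 1, 1, 1, 0),
                  c(1, 0, 0, 1, 0),
                  c(0, 0, 1, 1, 0))
  colnames(oral) <- colnames(faecal) <- paste0("g", 1:5)
  tabs <- mkPairedTables(oral, faecal, rep("HV", 3))
  res <- sharedGenusAnalysis(tabs$oral, tabs$faecal)
  # pooled: oral set {g1,g2,g3,g5}, faecal set {g1,g2,g3,g4}
  expect_equal(unname(res$HV$venn),
               c(1, 3, 1))  # oral-only g5; shared g1,g2,g3; faecal-only g4
  # subject 1: oral {1,2,5}, faecal {2,3,4}: shared 1 of union 5
  expect_equal(unname(res$HV$sharedPercent[1]), 100 / 5)

  # identical tables give 100% everywhere
  same <- mkPairedTables(oral, oral, rep("HV", 3))
  resSame <- sharedGenusAnalysis(same$oral, same$faecal)
  expect_true(all(resSame$HV$sharedPercent == 100))
  expect_equal(unname(resSame$HV$venn[c("oralOnly", "faecalOnly")]),
               c(0, 0))

  # permutation of genus columns leaves shared percentages unchanged
  perm <- sample(5)
  tabsPerm <- mkPairedTables(oral[, perm], faecal[, perm], rep("HV", 3))
  resPerm <- sharedGenusAnalysis(tabsPerm$oral, tabsPerm$faecal)
  expect_equal(resPerm$HV$sharedPercent, res$HV$sharedPercent)
})

test_that("disjoint namespaces share nothing and groups are compared", {
  oral <- matrix(1, 4, 3, dimnames = list(NULL, paste0("o", 1:3)))
  faecal <- matrix(1, 4, 3, dimnames = list(NULL, paste0("f", 1:3)))
  tabs <- mkPairedTables(oral, faecal, rep(c("HV", "MS"), each = 2))
  res <- sharedGenusAnalysis(tabs$oral, tabs$faecal)
  expect_equal(unname(res$HV$venn["shared"]), 0)
  expect_equal(unname(res$MS$venn["shared"]), 0)
  expect_true(!is.null(res$wilcoxonP))
})
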