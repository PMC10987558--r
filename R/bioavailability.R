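#' Bioavailability index: group fold change of community boundary fluxes
#'
#' For each extracellular metabolite, summarizes per-individual net exchange
#' fluxes (secretion-positive) per group and reports the log2 fold change
#' between the case and control summaries, a two-sided Wilcoxon rank-sum p
#' over the per-individual fluxes, and the permutation-based FDR q of
#' [permutationFDR()]. Because a ratio across a sign change is meaningless,
#' the fold change is computed on flux magnitudes with a pseudo-flux, and a
#' separate `switch` flag marks metabolites whose group summaries have
#' opposite signs (production in one group, consumption in the other). The
#' significance flag combines p < `pThreshold` and q < `fdrThreshold`.
#'
#' @param fluxMatrix samples x metabolites matrix of boundary fluxes (from
#'   [cohortFluxes()]`$fluxes`).
#' @param groups group label per sample (named or aligned with rows).
#' @param case,control labels of the two compared groups.
#' @param nPerm label permutations for the FDR (default 1000).
#' @param seed integer seed (mandatory).
#' @param pseudo pseudo-flux added to both magnitudes (> 0, default 1e-6).
#' @param summary `"mean"` (default) or `"median"` group summary.
#' @param pThreshold,fdrThreshold significance filter (defaults 0.05 and
#'   0.1).
#' @return `data.frame`, one row per metabolite: `metabolite`,
#'   `summaryCase`, `summaryControl`, `log2FC`, `switch`, `W`, `p`, `q`,
#'   `significant`.
#' @export
bioavailability <- function(fluxMatrix, groups, case, control,
                            nPerm = 1000, seed, pseudo = 1e-6,
                            summary = c("mean", "median"),
                            pThreshold = 0.05, fdrThreshold = 0.1) {
  summary <- match.arg(summary)
  if (missing(seed)) stop("a seed is required")
  assertScalarNumber(pseudo, "pseudo", lower = 1e-300)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(fluxMatrix))
  keep <- groups %in% c(case, control)
  X <- fluxMatrix[keep, , drop = FALSE]
  g <- groups[keep]
  if (sum(g == case) < 2 || sum(g == control) < 2)
    stop("each group needs at least 2 samples")
  if (ncol(X) == 0) stop("no metabolites in the flux profiles")
  summarize <- if (summary == "mean") colMeans else
    function(m) apply(m, 2, stats::median)
  sCase <- summarize(X[g == case, , drop = FALSE])
  sCtrl <- summarize(X[g == control, , drop = FALSE])
  log2FC <- log2((abs(sCase) + pseudo) / (abs(sCtrl) + pseudo))
  switch_ <- sign(sCase) != sign(sCtrl) & sCase != 0 & sCtrl != 0
  prep <- rankSumPrepare(X)
  idx1 <- which(g == case)
  obs <- rankSumTest(prep, idx1)
  pPerm <- withSeed(substreamSeed(seed, "bioavailability"), {
    vapply(seq_len(nPerm), function(b)
      rankSumTest(prep, sample(nrow(X), length(idx1)))$p,
      numeric(ncol(X)))
  })
  if (is.null(dim(pPerm))) pPerm <- matrix(pPerm, nrow = ncol(X))
  q <- permutationFDR(obs$p, pPerm)
  data.frame(metabolite = colnames(X),
             summaryCase = unname(sCase), summaryControl = unname(sCtrl),
             log2FC = unname(log2FC), switch = unname(switch_),
             W = unname(obs$W), p = unname(obs$p), q = q,
             significant = unname(obs$p < pThreshold & q < fdrThreshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected bioavailability directions implied by planted genera
#'
#' Combines a training truth with a model library's signature map to derive,
#' per signature metabolite, the expected direction of the case-vs-control
#' flux difference: a planted "up" genus that secretes a metabolite raises
#' case-side net secretion, a planted "up" consumer lowers it, and vice
#' versa for "down". The result is stored in the truth as
#' `expectedBioavailability` and drives downstream recovery checks.
#'
#' @param truth a `syntheticTruth` from [generateCohort()].
#' @param models a model library from [generateModelLibrary()].
#' @return the truth with an `expectedBioavailability` data.frame
#'   (`metabolite`, `expectedSign`).
#' @export
linkTruthToLibrary <- function(truth, models) {
  stopifnot(inherits(truth, "syntheticTruth"))
  sm <- attr(models, "signatureMap")
  if (is.null(sm)) stop("model library lacks a signatureMap attribute")
  planted <- truth$plantedGenera
  if (is.null(planted) || !nrow(planted)) {
    truth$expectedBioavailability <- data.frame(metabolite = character(0),
                                                expectedSign = numeric(0))
    return(truth)
  }
  mets <- unique(sm$metabolite)
  delta <- stats::setNames(numeric(length(mets)), mets)
  for (i in seq_len(nrow(planted))) {
    g <- planted$genus[i]
    row <- sm[sm$taxon == g, , drop = FALSE]
    if (!nrow(row)) next
    factor <- if (planted$direction[i] == "up") planted$fold[i] - 1
              else 1 / planted$fold[i] - 1
    delta[row$metabolite] <- delta[row$metabolite] +
      factor * row$soloFlux
  }
  affected <- delta[delta != 0]
  truth$expectedBioavailability <- data.frame(
    metabolite = names(affected), expectedSign = sign(unname(affected)),
    stringsAsFactors = FALSE)
  truth$informativeFeatures <- names(affected)
  truth
}
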