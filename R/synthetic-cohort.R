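#' Specification of a synthetic two-group cohort
#'
#' Describes a compositional genus-level cohort generated by
#' [generateCohort()]: Dirichlet-multinomial counts for a control and a case
#' group, with chosen genera planted as enriched ("up") or depleted ("down")
#' in cases by a fold effect applied to the Dirichlet mean proportions
#' before renormalization (realized fold changes are therefore slightly
#' attenuated by compositional closure).
#'
#' @param nPerGroup samples per group (>= 2).
#' @param nGenera number of genera.
#' @param plantedGenera data.frame with columns `genus`, `direction`
#'   (`"up"`/`"down"`) and `fold` (> 0); may have zero rows.
#' @param dispersion Dirichlet concentration scalar (> 0): larger values
#'   give less sample-to-sample overdispersion.
#' @param readDepth expected per-sample total count (Poisson).
#' @param seed integer seed.
#' @param groups labels of the two groups; effects are planted in the
#'   second (case) group.
#' @return a `cohortSpec` list, validated.
#' @export
cohortSpec <- function(nPerGroup = 20, nGenera = 40,
                       plantedGenera = data.frame(), dispersion = 50,
                       readDepth = 1e4, seed,
                       groups = c("HV", "MS")) {
  assertScalarNumber(nPerGroup, "nPerGroup", lower = 2, integer = TRUE)
  assertScalarNumber(nGenera, "nGenera", lower = 2, integer = TRUE)
  assertScalarNumber(dispersion, "dispersion", lower = 1e-9)
  assertScalarNumber(readDepth, "readDepth", lower = 10)
  if (missing(seed)) stop("a seed is required")
  assertScalarNumber(seed, "seed", integer = TRUE)
  if (nrow(plantedGenera)) {
    stopifnot(all(c("genus", "direction", "fold") %in% names(plantedGenera)))
    if (!all(plantedGenera$direction %in% c("up", "down")))
      stop("planted directions must be 'up' or 'down'")
    if (any(plantedGenera$fold <= 0)) stop("fold effects must be > 0")
    if (!all(plantedGenera$genus %in% genusNames(nGenera)))
      stop("planted genera must belong to the genus set")
  }
  structure(list(nPerGroup = as.integer(nPerGroup),
                 nGenera = as.integer(nGenera),
                 plantedGenera = plantedGenera, dispersion = dispersion,
                 readDepth = readDepth, seed = as.integer(seed),
                 groups = groups),
            class = "cohortSpec")
}

genusNames <- function(n) sprintf("g%03d", seq_len(n))

# Base mean proportions: geometric ranks, mimicking the steep rank-abundance
# curves of genus-level 16S tables (a few dominant genera, a long tail).
baseProportions <- function(nGenera, seed) {
  withSeed(substreamSeed(seed, "base-proportions"), {
    raw <- exp(stats::rnorm(nGenera, mean = -0.08 * seq_len(nGenera),
                            sd = 0.4))
    raw / sum(raw)
  })
}

# Apply planted fold effects to mean proportions (before renormalization).
plantEffects <- function(pi0, planted) {
  pi1 <- pi0
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      g <- planted$genus[i]
      f <- planted$fold[i]
      pi1[g] <- if (planted$direction[i] == "up") pi1[g] * f else pi1[g] / f
      if (pi1[g] > 1)
        stop(sprintf(
          "fold effect on '%s' drives its proportion above 1; reject spec",
          g))
    }
  }
  pi1 / sum(pi1)
}

drawGroup <- function(n, piMean, dispersion, readDepth, prefix, seed) {
  withSeed(seed, {
    P <- rdirichlet(n, dispersion * piMean)
    depth <- stats::rpois(n, readDepth)
    counts <- vapply(seq_len(n), function(i)
      as.numeric(stats::rmultinom(1, depth[i], P[i, ])),
      numeric(length(piMean)))
    dimnames(counts) <- list(names(piMean), sprintf("%s%02d", prefix,
                                                    seq_len(n)))
    counts
  })
}

#' Generate a synthetic two-group cohort with planted differential genera
#'
#' Counts are Dirichlet-multinomial: per-sample genus proportions are drawn
#' from a Dirichlet around the group mean (concentration =
#' `dispersion`), then counts from a multinomial at a Poisson read depth.
#' Identical spec and seed give bitwise-identical tables.
#'
#' @param spec a [cohortSpec()].
#' @param cohort cohort label written into the sample metadata
#'   (default "training").
#' @return list with `table` (an [AbundanceTable-class] of counts, with
#'   subject, group, age, sex and cohort metadata) and `truth` (a
#'   `syntheticTruth` list recording the planted genera and directions).
#' @export
generateCohort <- function(spec, cohort = "training") {
  stopifnot(inherits(spec, "cohortSpec"))
  genera <- genusNames(spec$nGenera)
  pi0 <- stats::setNames(baseProportions(spec$nGenera, spec$seed), genera)
  pi1 <- plantEffects(pi0, spec$plantedGenera)
  c0 <- drawGroup(spec$nPerGroup, pi0, spec$dispersion, spec$readDepth,
                  "ctrl", substreamSeed(spec$seed, "group-control"))
  c1 <- drawGroup(spec$nPerGroup, pi1, spec$dispersion, spec$readDepth,
                  "case", substreamSeed(spec$seed, "group-case"))
  counts <- cbind(c0, c1)
  n <- ncol(counts)
  meta <- withSeed(substreamSeed(spec$seed, "metadata"), data.frame(
    sample_id = colnames(counts),
    subject_id = paste0("subj_", colnames(counts)),
    group = rep(spec$groups, each = spec$nPerGroup),
    compartment = "oral",
    age = round(stats::runif(n, 25, 65), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    cohort = cohort, stringsAsFactors = FALSE))
  table <- abundanceTable(counts, sampleData = meta)
  truth <- structure(list(
    plantedGenera = spec$plantedGenera,
    groups = spec$groups,
    caseGroup = spec$groups[2],
    baseProportions = pi0,
    caseProportions = pi1,
    expectedBioavailability = NULL,
    informativeFeatures = NULL), class = "syntheticTruth")
  list(table = table, truth = truth)
}

#' Specification of a paired oral/faecal cohort
#'
#' @param oral,faecal [cohortSpec()] objects for the two compartments (same
#'   `nPerGroup` and groups).
#' @param sharedGenusFraction named numeric (one entry per group) in
#'   \[0, 1\]: target fraction of the genus union resident in both
#'   compartments for that group.
#' @param crossCorrelation data.frame with columns `oralGenus`,
#'   `faecalGenus`, `sign` (+1/-1): cross-compartment abundance
#'   correlations to induce via a shared per-subject latent factor.
#' @return a `pairedCohortSpec` list.
#' @export
pairedCohortSpec <- function(oral, faecal,
                             sharedGenusFraction = c(HV = 0.12, MS = 0.18),
                             crossCorrelation = data.frame()) {
  stopifnot(inherits(oral, "cohortSpec"), inherits(faecal, "cohortSpec"))
  if (oral$nPerGroup != faecal$nPerGroup)
    stop("oral and faecal specs must have the same nPerGroup")
  if (!identical(oral$groups, faecal$groups))
    stop("oral and faecal specs must use the same groups")
  if (any(sharedGenusFraction < 0 | sharedGenusFraction > 1))
    stop("sharedGenusFraction must be in [0, 1]")
  if (!identical(sort(names(sharedGenusFraction)), sort(oral$groups)))
    stop("sharedGenusFraction must name every group")
  if (nrow(crossCorrelation)) {
    stopifnot(all(c("oralGenus", "faecalGenus", "sign") %in%
                    names(crossCorrelation)))
    if (!all(crossCorrelation$oralGenus %in% genusNames(oral$nGenera)))
      stop("correlation requested for absent oral genus")
    if (!all(crossCorrelation$faecalGenus %in% genusNames(faecal$nGenera)))
      stop("correlation requested for absent faecal genus")
  }
  structure(list(oral = oral, faecal = faecal,
                 sharedGenusFraction = sharedGenusFraction,
                 crossCorrelation = crossCorrelation),
            class = "pairedCohortSpec")
}

#' Generate a paired oral/faecal cohort
#'
#' The same subjects are sampled in both compartments. Compartment genus
#' namespaces overlap by a controllable amount: for each group, the number
#' of genera resident in both compartments is chosen so that the expected
#' shared fraction |both| / |either| matches `sharedGenusFraction`.
#' Requested cross-compartment correlations are induced by scaling the two
#' genera's Dirichlet means with a shared per-subject log-normal factor
#' (same factor for sign +1, reciprocal for sign -1).
#'
#' @param spec a [pairedCohortSpec()].
#' @return list with `oral` and `faecal` [AbundanceTable-class] objects and
#'   a shared `truth`.
#' @export
generatePairedCohort <- function(spec) {
  stopifnot(inherits(spec, "pairedCohortSpec"))
  so <- spec$oral
  sf <- spec$faecal
  groups <- so$groups
  n <- so$nPerGroup
  oralGenera <- genusNames(so$nGenera)
  faecalGenera <- genusNames(sf$nGenera)
  piO <- stats::setNames(baseProportions(so$nGenera, so$seed), oralGenera)
  piF <- stats::setNames(baseProportions(sf$nGenera, sf$seed + 1L),
                         faecalGenera)
  piO1 <- plantEffects(piO, so$plantedGenera)
  piF1 <- plantEffects(piF, sf$plantedGenera)

  resident <- function(frac, seed) {
    # every genus stays resident in at least one compartment, so the union
    # of residents is the whole namespace union U and the shared fraction
    # |both| / U is controlled by the shared-set size s = frac * U.
    # Genera carrying a requested cross-compartment correlation must be
    # resident in both compartments, so they are forced into the shared set.
    U <- length(union(oralGenera, faecalGenera))
    common <- intersect(oralGenera, faecalGenera)
    s <- min(round(frac * U), length(common))
    cc <- spec$crossCorrelation
    forced <- if (nrow(cc)) intersect(common, c(cc$oralGenus,
                                                cc$faecalGenus))
              else character(0)
    s <- max(s, length(forced))
    withSeed(seed,
             c(forced, sample(setdiff(common, forced), s - length(forced))))
  }

  makeCounts <- function(piMeanO, piMeanF, shared, nSub, prefix, seed) {
    # zero out non-shared genera in the opposite compartment resident set:
    # oral residents = oral namespace; of the common namespace only the
    # 'shared' genera stay resident in both
    common <- intersect(names(piMeanO), names(piMeanF))
    oralOnlyDrop <- setdiff(common, shared)
    # split the common non-shared genera between the compartments
    half <- length(oralOnlyDrop) %/% 2
    dropFromOral <- oralOnlyDrop[seq_len(half)]
    dropFromFaecal <- setdiff(oralOnlyDrop, dropFromOral)
    pO <- piMeanO
    pO[dropFromOral] <- 0
    pF <- piMeanF
    pF[dropFromFaecal] <- 0
    pO <- pO / sum(pO)
    pF <- pF / sum(pF)
    withSeed(seed, {
      latent <- exp(stats::rnorm(nSub, 0, 0.8))
      cO <- matrix(0, length(pO), nSub,
                   dimnames = list(names(pO),
                                   sprintf("%s%02d_oral", prefix,
                                           seq_len(nSub))))
      cF <- matrix(0, length(pF), nSub,
                   dimnames = list(names(pF),
                                   sprintf("%s%02d_faecal", prefix,
                                           seq_len(nSub))))
      for (i in seq_len(nSub)) {
        pOi <- pO
        pFi <- pF
        cc <- spec$crossCorrelation
        if (nrow(cc)) for (r in seq_len(nrow(cc))) {
          fac <- latent[i]
          pOi[cc$oralGenus[r]] <- pOi[cc$oralGenus[r]] * fac
          pFi[cc$faecalGenus[r]] <- pFi[cc$faecalGenus[r]] *
            (if (cc$sign[r] >= 0) fac else 1 / fac)
        }
        pOi <- pOi / sum(pOi)
        pFi <- pFi / sum(pFi)
        probO <- rdirichlet(1, so$dispersion * pOi)[1, ]
        probO[pOi == 0] <- 0
        probO <- probO / sum(probO)
        probF <- rdirichlet(1, sf$dispersion * pFi)[1, ]
        probF[pFi == 0] <- 0
        probF <- probF / sum(probF)
        cO[, i] <- stats::rmultinom(1, stats::rpois(1, so$readDepth), probO)
        cF[, i] <- stats::rmultinom(1, stats::rpois(1, sf$readDepth), probF)
      }
      list(oral = cO, faecal = cF)
    })
  }

  oralCounts <- faecalCounts <- list()
  meta <- list()
  prefixes <- c("ctrl", "case")
  for (gi in seq_along(groups)) {
    shared <- resident(spec$sharedGenusFraction[[groups[gi]]],
                       substreamSeed(so$seed, paste0("shared-", groups[gi])))
    pm <- makeCounts(if (gi == 1) piO else piO1,
                     if (gi == 1) piF else piF1,
                     shared, n, prefixes[gi],
                     substreamSeed(so$seed, paste0("paired-", groups[gi])))
    oralCounts[[gi]] <- pm$oral
    faecalCounts[[gi]] <- pm$faecal
    meta[[gi]] <- data.frame(
      subject = sprintf("%s%02d", prefixes[gi], seq_len(n)),
      group = groups[gi], stringsAsFactors = FALSE)
  }
  subj <- do.call(rbind, meta)
  ages <- withSeed(substreamSeed(so$seed, "paired-ages"),
                   round(stats::runif(nrow(subj), 25, 65), 1))
  mkMeta <- function(counts, compartment) data.frame(
    sample_id = colnames(counts), subject_id = subj$subject,
    group = subj$group, compartment = compartment, age = ages,
    sex = "F", cohort = "training", stringsAsFactors = FALSE)
  oc <- do.call(cbind, oralCounts)
  fc <- do.call(cbind, faecalCounts)
  truth <- structure(list(
    sharedGenusFraction = spec$sharedGenusFraction,
    crossCorrelation = spec$crossCorrelation,
    plantedGenera = so$plantedGenera, groups = groups,
    caseGroup = groups[2]), class = "syntheticTruth")
  list(oral = abundanceTable(oc, mkMeta(oc, "oral")),
       faecal = abundanceTable(fc, mkMeta(fc, "faecal")),
       truth = truth)
}

#' Generate an independent validation cohort with the same planted signal
#'
#' Re-generates a cohort carrying the training truth's planted genera and
#' directions, from an independent seed, and applies a cohort-level batch
#' effect: every genus mean is tilted by `exp(shift * delta_g)` with a
#' fixed unit-norm direction `delta` drawn once per cohort. At `shift = 0`
#' the generator is distributionally identical to the training generator;
#' nonzero shifts displace all downstream features (including inferred
#' fluxes) coherently, emulating a between-cohort batch effect that
#' per-cohort mean-centering should largely remove.
#'
#' @param spec a [cohortSpec()] for the validation cohort (use a different
#'   seed from training).
#' @param truth the `syntheticTruth` from the training generation; its
#'   planted signal replaces `spec$plantedGenera`.
#' @param shift magnitude of the batch tilt (default 0).
#' @return list with `table` and `truth` as in [generateCohort()].
#' @export
generateValidationCohort <- function(spec, truth, shift = 0) {
  stopifnot(inherits(spec, "cohortSpec"),
            inherits(truth, "syntheticTruth"))
  assertScalarNumber(shift, "shift", lower = 0)
  spec$plantedGenera <- truth$plantedGenera
  genera <- genusNames(spec$nGenera)
  pi0 <- stats::setNames(baseProportions(spec$nGenera, spec$seed), genera)
  if (shift > 0) {
    delta <- withSeed(substreamSeed(spec$seed, "batch-direction"), {
      d <- stats::rnorm(spec$nGenera)
      d / sqrt(sum(d^2))
    })
    pi0 <- pi0 * exp(shift * delta)
    pi0 <- pi0 / sum(pi0)
  }
  pi1 <- plantEffects(pi0, spec$plantedGenera)
  c0 <- drawGroup(spec$nPerGroup, pi0, spec$dispersion, spec$readDepth,
                  "vctrl", substreamSeed(spec$seed, "group-control"))
  c1 <- drawGroup(spec$nPerGroup, pi1, spec$dispersion, spec$readDepth,
                  "vcase", substreamSeed(spec$seed, "group-case"))
  counts <- cbind(c0, c1)
  n <- ncol(counts)
  meta <- withSeed(substreamSeed(spec$seed, "metadata"), data.frame(
    sample_id = colnames(counts),
    subject_id = paste0("subj_", colnames(counts)),
    group = rep(spec$groups, each = spec$nPerGroup),
    compartment = "oral",
    age = round(stats::runif(n, 25, 65), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    cohort = "validation", stringsAsFactors = FALSE))
  newTruth <- truth
  newTruth$batchShift <- shift
  list(table = abundanceTable(counts, sampleData = meta), truth = newTruth)
}
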