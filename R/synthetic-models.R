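#' Specification of a toy metabolic model library
#'
#' Each taxon gets a minimal three-compartment reconstruction (its own
#' cytosol, the shared extracellular space, and the boundary): uptake of a
#' private substrate, an internal conversion to a growth objective, and a
#' signature extracellular metabolite that the taxon secretes or consumes
#' in fixed proportion to growth. Because the signature flux is
#' stoichiometrically coupled to the objective, a taxon's optimal boundary
#' flux for its signature metabolite is proportional to its abundance
#' weight in any community, which is what makes planted abundance shifts
#' imply known bioavailability shifts.
#'
#' @param taxa character vector of taxon ids (default `g001`, `g002`, ...
#'   matching the synthetic cohort genus names).
#' @param nExtracellularMetabolites number of shared signature metabolites
#'   (`m01_e`, ...); taxa are assigned signatures round-robin.
#' @param signatureMap optional data.frame with columns `taxon`,
#'   `metabolite`, `mode` (`"secrete"`/`"consume"`) overriding the
#'   round-robin assignment.
#' @param seed integer seed (randomizes uptake capacities and coupling
#'   coefficients).
#' @return a `modelLibrarySpec` list.
#' @export
modelLibrarySpec <- function(taxa = genusNames(10),
                             nExtracellularMetabolites = 5,
                             signatureMap = NULL, seed) {
  if (missing(seed)) stop("a seed is required")
  assertScalarNumber(seed, "seed", integer = TRUE)
  assertScalarNumber(nExtracellularMetabolites, "nExtracellularMetabolites",
                     lower = 1, integer = TRUE)
  mets <- sprintf("m%02d_e", seq_len(nExtracellularMetabolites))
  if (is.null(signatureMap)) {
    signatureMap <- data.frame(
      taxon = taxa,
      metabolite = mets[(seq_along(taxa) - 1) %% length(mets) + 1],
      mode = rep(c("secrete", "consume"),
                 length.out = length(taxa)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("taxon", "metabolite", "mode") %in% names(signatureMap)))
  if (!all(signatureMap$mode %in% c("secrete", "consume")))
    stop("signature modes must be 'secrete' or 'consume'")
  if (!all(signatureMap$metabolite %in% mets))
    stop("signature metabolites must exist in the shared extracellular namespace")
  if (!all(signatureMap$taxon %in% taxa))
    stop("signature map names unknown taxa")
  structure(list(taxa = taxa,
                 nExtracellularMetabolites = nExtracellularMetabolites,
                 metabolites = mets, signatureMap = signatureMap,
                 seed = as.integer(seed)),
            class = "modelLibrarySpec")
}

# One toy reconstruction: private substrate sub_<t>_e, cytosolic precursor
# <t>_A, growth objective coupled to the signature metabolite.
buildToyModel <- function(taxon, signature, mode, uptakeCap, couple) {
  sub <- paste0("sub_", taxon, "_e")
  A <- paste0(taxon, "_A")
  sgn <- if (mode == "secrete") couple else -couple
  metabolicReconstruction(
    taxonId = taxon,
    metabolites = data.frame(
      id = c(sub, signature, A),
      compartment = c("extracellular", "extracellular", "internal"),
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_sub", "EX_sig", "UPT", "GROWTH"),
      stoich = I(list(
        stats::setNames(-1, sub),
        stats::setNames(-1, signature),
        stats::setNames(c(-1, 1), c(sub, A)),
        stats::setNames(c(-1, sgn), c(A, signature)))),
      lb = c(-uptakeCap, -uptakeCap, 0, 0),
      ub = c(0, 1000, 1000, 1000),
      exchange = c(TRUE, TRUE, FALSE, FALSE),
      objective = c(0, 0, 0, 1),
      stringsAsFactors = FALSE))
}

#' Generate a toy metabolic model library with known signatures
#'
#' Builds one [MetabolicReconstruction-class] per taxon according to the
#' spec, then verifies each by solo flux balance analysis: the generator
#' fails loudly if any model is infeasible, has a non-positive optimum, or
#' does not move its signature metabolite in the declared direction.
#'
#' @param spec a [modelLibrarySpec()].
#' @return named list of reconstructions (taxon id -> model) with a
#'   `signatureMap` attribute giving each taxon's metabolite, mode and
#'   solo signature flux.
#' @export
generateModelLibrary <- function(spec) {
  stopifnot(inherits(spec, "modelLibrarySpec"))
  pars <- withSeed(substreamSeed(spec$seed, "model-library"), {
    n <- length(spec$taxa)
    # uptake capacities stay below the default community medium cap (10)
    # so merging into a community never tightens a member's own bounds
    list(uptake = stats::runif(n, 4, 9),
         couple = stats::runif(n, 0.3, 0.7))
  })
  models <- vector("list", length(spec$taxa))
  soloFlux <- numeric(length(spec$taxa))
  for (k in seq_along(spec$taxa)) {
    t <- spec$taxa[k]
    sig <- spec$signatureMap[spec$signatureMap$taxon == t, , drop = FALSE]
    if (nrow(sig) != 1)
      stop(sprintf("taxon '%s' needs exactly one signature", t))
    m <- buildToyModel(t, sig$metabolite, sig$mode,
                       pars$uptake[k], pars$couple[k])
    sol <- fba(m)
    if (solutionStatus(sol) != "optimal" || objectiveValue(sol) <= 0)
      stop(sprintf("generated model for '%s' is infeasible", t))
    bf <- boundaryFluxes(sol, m)
    want <- if (sig$mode == "secrete") 1 else -1
    if (sign(bf[[sig$metabolite]]) != want)
      stop(sprintf("model for '%s' does not %s its signature metabolite",
                   t, sig$mode))
    soloFlux[k] <- bf[[sig$metabolite]]
    models[[k]] <- m
  }
  out <- stats::setNames(models, spec$taxa)
  sm <- spec$signatureMap
  sm$soloFlux <- soloFlux[match(sm$taxon, spec$taxa)]
  attr(out, "signatureMap") <- sm
  out
}
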