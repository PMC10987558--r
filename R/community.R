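#' Select taxa for metabolic modelling
#'
#' Genera whose relative abundance is strictly greater than `threshold`
#' (default 1%) in at least one sample: these are the taxa whose
#' reconstructions enter the per-individual community models.
#'
#' @param table normalized [AbundanceTable-class].
#' @param threshold relative-abundance cutoff (default 0.01, strict
#'   inequality).
#' @return character vector of genus ids.
#' @export
selectTaxa <- function(table, threshold = 0.01) {
  stopifnot(is(table, "AbundanceTable"))
  if (!isNormalized(table))
    stop("selectTaxa expects a normalized table; see toRelative()")
  a <- abundances(table)
  rownames(a)[apply(a > threshold, 1, any)]
}

#' Merge per-taxon reconstructions into an abundance-weighted community model
#'
#' Each member's metabolites and reactions are namespaced as
#' `<taxon>__<id>`. Extracellular metabolites with identical ids are pooled
#' into a shared compartment; each member's exchange reactions become
#' transfer reactions between its own (namespaced) extracellular metabolite
#' and the pool, keeping the member's exchange bounds. All member reaction
#' bounds and objective coefficients are scaled by the member's renormalized
#' relative abundance, so a taxon at weight 1 reproduces its solo model and
#' non-interacting taxa contribute additively. One community exchange
#' reaction (`EX_<metabolite>`) per pooled metabolite connects the pool to
#' the environment with the medium bounds.
#'
#' @param models list of [MetabolicReconstruction-class] with distinct
#'   taxon ids.
#' @param abundances named per-taxon relative abundances for one sample;
#'   every model taxon must be present with non-negative abundance and a
#'   positive total.
#' @param medium length-2 numeric `c(lb, ub)` for community exchange
#'   reactions; default `c(-10, 1000)` (arbitrary flux units, uptake
#'   capped at 10).
#' @return a [CommunityModel-class]; its `coverage` slot records the sum of
#'   the unrenormalized abundances of the modelled taxa.
#' @export
buildCommunityModel <- function(models, abundances, medium = c(-10, 1000)) {
  taxa <- vapply(models, taxonId, "")
  if (anyDuplicated(taxa)) stop("duplicate taxon ids in model list")
  if (!all(taxa %in% names(abundances)))
    stop("abundances missing for taxa: ",
         paste(setdiff(taxa, names(abundances)), collapse = ", "))
  w0 <- abundances[taxa]
  if (any(w0 < 0)) stop("negative abundances")
  if (sum(w0) <= 0) stop("zero total modelled abundance")
  w <- unname(w0 / sum(w0))
  coverage <- min(1, sum(w0))

  poolIds <- character(0)
  metList <- list()
  rxnList <- list()
  for (k in seq_along(models)) {
    m <- models[[k]]
    t <- taxa[k]
    met <- m@metabolites
    rxn <- m@reactions
    ext <- met$compartment == "extracellular"
    poolIds <- union(poolIds, met$id[ext])
    # namespace every member metabolite (extracellular ones become the
    # member's own periplasm-like node, connected to the pool by transfers)
    rename <- stats::setNames(paste0(t, "__", met$id), met$id)
    metList[[k]] <- data.frame(id = unname(rename),
                               compartment = "internal",
                               stringsAsFactors = FALSE)
    newRxn <- rxn
    newRxn$id <- paste0(t, "__", rxn$id)
    newRxn$lb <- rxn$lb * w[k]
    newRxn$ub <- rxn$ub * w[k]
    newRxn$objective <- rxn$objective * w[k]
    stoich <- vector("list", nrow(rxn))
    for (i in seq_len(nrow(rxn))) {
      s <- rxn$stoich[[i]]
      s2 <- stats::setNames(unname(s), rename[names(s)])
      if (rxn$exchange[i]) {
        # solo boundary -> pool transfer: positive flux still means the
        # member releases the metabolite (now into the shared pool)
        metId <- names(rxn$stoich[[i]])
        s2 <- c(s2, stats::setNames(-unname(s), metId))
      }
      stoich[[i]] <- s2
    }
    newRxn$stoich <- I(stoich)
    newRxn$exchange <- FALSE
    rxnList[[k]] <- newRxn
  }
  poolMet <- data.frame(id = poolIds, compartment = "extracellular",
                        stringsAsFactors = FALSE)
  exRxn <- data.frame(id = paste0("EX_", poolIds),
                      lb = medium[1], ub = medium[2],
                      exchange = TRUE, objective = 0,
                      stringsAsFactors = FALSE)
  exRxn$stoich <- I(lapply(poolIds, function(p) stats::setNames(-1, p)))

  allMet <- rbind(do.call(rbind, metList), poolMet)
  allRxn <- rbind(do.call(rbind, rxnList),
                  exRxn[, c("id", "lb", "ub", "exchange", "objective",
                            "stoich")])
  obj <- new("CommunityModel",
             taxa = unname(taxa), weights = w, coverage = coverage,
             metabolites = allMet, reactions = allRxn)
  validObject(obj)
  obj
}

#' @rdname accessors
#' @export
setMethod("memberWeights", "CommunityModel", function(x)
  stats::setNames(x@weights, x@taxa))

#' @rdname accessors
#' @export
setMethod("coverage", "CommunityModel", function(x) x@coverage)

setMethod("show", "CommunityModel", function(object) {
  cat(sprintf("CommunityModel: %d taxa, coverage %.3f, %d reactions\n",
              length(object@taxa), object@coverage,
              nrow(object@reactions)))
})

#' Per-sample community flux profiles for a cohort
#'
#' For every sample: select the modelled taxa (cohort-level > 1% rule via
#' [selectTaxa()] intersected with the model library), build the
#' abundance-weighted community model, solve parsimonious FBA and extract
#' boundary fluxes. Samples whose coverage falls below `coverageFloor` are
#' flagged, never dropped.
#'
#' @param table normalized [AbundanceTable-class].
#' @param models named list of [MetabolicReconstruction-class] (taxon id ->
#'   model).
#' @param threshold taxon-selection cutoff (default 0.01).
#' @param coverageFloor minimum acceptable coverage (default 0.5).
#' @param medium community exchange bounds, see [buildCommunityModel()].
#' @return list with `fluxes` (samples x metabolites matrix of net exchange
#'   fluxes, secretion-positive), `coverage` (per sample), `flagged`
#'   (logical per sample), `selectedTaxa`.
#' @export
cohortFluxes <- function(table, models, threshold = 0.01,
                         coverageFloor = 0.5, medium = c(-10, 1000)) {
  stopifnot(is(table, "AbundanceTable"))
  sel <- selectTaxa(table, threshold)
  modelled <- intersect(sel, names(models))
  if (!length(modelled)) stop("no selected taxon has a reconstruction")
  a <- abundances(table)
  samples <- colnames(a)
  profiles <- vector("list", length(samples))
  cov <- numeric(length(samples))
  for (i in seq_along(samples)) {
    ab <- a[, i]
    present <- modelled[ab[modelled] > 0]
    if (!length(present))
      stop(sprintf("sample '%s' has zero modelled taxa", samples[i]))
    cm <- buildCommunityModel(models[present], ab[present], medium = medium)
    cov[i] <- min(1, sum(ab[modelled]))
    sol <- fba(cm)
    if (solutionStatus(sol) != "optimal")
      stop(sprintf("community FBA %s for sample '%s'",
                   solutionStatus(sol), samples[i]))
    profiles[[i]] <- boundaryFluxes(sol, cm)
  }
  mets <- sort(unique(unlist(lapply(profiles, names))))
  flux <- matrix(0, nrow = length(samples), ncol = length(mets),
                 dimnames = list(samples, mets))
  for (i in seq_along(samples))
    flux[i, names(profiles[[i]])] <- profiles[[i]]
  list(fluxes = flux, coverage = stats::setNames(cov, samples),
       flagged = stats::setNames(cov < coverageFloor, samples),
       selectedTaxa = modelled)
}
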