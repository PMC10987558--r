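#' AbundanceTable: genus-level abundance matrix with sample metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' non-negative genera-by-samples matrix in the `"abundance"` assay, sample
#' metadata (subject, group, compartment, age, sex, cohort) in `colData`, and
#' a flag recording whether values are per-sample relative abundances.
#'
#' Rows are genera and columns are samples, following the Bioconductor
#' convention that rows index features.
#'
#' @slot normalized logical; `TRUE` when every column sums to one (within
#'   1e-9) and values are proportions rather than read counts.
#' @export
setClass("AbundanceTable",
  contains = "SummarizedExperiment",
  representation(normalized = "logical"),
  prototype(normalized = FALSE)
)

setValidity("AbundanceTable", function(object) {
  a <- SummarizedExperiment::assay(object, "abundance")
  if (!is.numeric(a)) return("abundance assay must be numeric")
  if (anyNA(a) || any(!is.finite(a))) return("abundance values must be finite")
  if (any(a < 0)) return("abundance values must be non-negative")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("genus (row) and sample (column) names are required")
  if (anyDuplicated(rownames(a))) return("duplicate genus ids")
  if (anyDuplicated(colnames(a))) return("duplicate sample ids")
  if (length(object@normalized) != 1L || is.na(object@normalized))
    return("'normalized' must be TRUE or FALSE")
  if (object@normalized) {
    cs <- colSums(a)
    if (any(abs(cs - 1) > 1e-9))
      return("normalized table has sample sums differing from 1 by > 1e-9")
  }
  TRUE
})

#' MetabolicModel: stoichiometric model shared representation
#'
#' Base class holding metabolites (id, compartment) and reactions (id,
#' stoichiometry as a list of named coefficient vectors, bounds, exchange
#' flag, objective coefficient). [MetabolicReconstruction-class] adds a taxon
#' identity; [CommunityModel-class] adds member taxa, weights and coverage.
#'
#' @slot metabolites data.frame with columns `id`, `compartment`
#'   (`"internal"` or `"extracellular"`).
#' @slot reactions data.frame with columns `id`, `lb`, `ub`, `exchange`
#'   (logical), `objective` (numeric coefficient) and a list column `stoich`
#'   of named numeric vectors (metabolite id -> coefficient).
#' @export
setClass("MetabolicModel",
  representation(metabolites = "data.frame", reactions = "data.frame")
)

validateStoichModel <- function(object) {
  met <- object@metabolites
  rxn <- object@reactions
  if (!all(c("id", "compartment") %in% names(met)))
    return("metabolites need columns 'id' and 'compartment'")
  if (!all(met$compartment %in% c("internal", "extracellular")))
    return("unknown compartment tag (must be 'internal' or 'extracellular')")
  if (anyDuplicated(met$id)) return("duplicate metabolite ids")
  need <- c("id", "stoich", "lb", "ub", "exchange", "objective")
  if (!all(need %in% names(rxn)))
    return(sprintf("reactions need columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(rxn$id)) return("duplicate reaction ids")
  if (any(!is.finite(rxn$lb)) || any(!is.finite(rxn$ub)))
    return("reaction bounds must be finite")
  if (any(rxn$lb > rxn$ub)) {
    bad <- rxn$id[rxn$lb > rxn$ub][1]
    return(sprintf("reaction '%s' has lb > ub", bad))
  }
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoich[[i]]
    if (length(s) == 0 || is.null(names(s)))
      return(sprintf("reaction '%s' has empty stoichiometry", rxn$id[i]))
    if (!all(names(s) %in% met$id))
      return(sprintf("reaction '%s' references unknown metabolites",
                     rxn$id[i]))
    if (rxn$exchange[i]) {
      if (length(s) != 1L)
        return(sprintf(
          "exchange reaction '%s' must touch exactly one metabolite",
          rxn$id[i]))
      comp <- met$compartment[match(names(s), met$id)]
      if (comp != "extracellular")
        return(sprintf(
          "exchange reaction '%s' must touch an extracellular metabolite",
          rxn$id[i]))
    }
  }
  if (all(rxn$objective == 0))
    return("model needs at least one nonzero objective coefficient")
  TRUE
}

setValidity("MetabolicModel", validateStoichModel)

#' MetabolicReconstruction: per-taxon stoichiometric model
#'
#' @slot taxonId single character taxon (genus) identifier.
#' @seealso [readModel()], [writeModel()], [fba()]
#' @export
setClass("MetabolicReconstruction",
  contains = "MetabolicModel",
  representation(taxonId = "character")
)

setValidity("MetabolicReconstruction", function(object) {
  if (length(object@taxonId) != 1L || !nzchar(object@taxonId))
    return("taxonId must be a single non-empty string")
  TRUE
})

#' CommunityModel: abundance-weighted merged community model
#'
#' Internal reactions and metabolites of each member taxon are namespaced as
#' `<taxon>__<id>`; extracellular metabolites with identical ids are pooled
#' in a shared compartment, with one community exchange reaction per pooled
#' metabolite. Member reaction bounds and objective contributions are scaled
#' by each taxon's renormalized relative abundance.
#'
#' @slot taxa character vector of member taxon ids.
#' @slot weights renormalized member weights (sum to one).
#' @slot coverage sum of unrenormalized member abundances: the fraction of
#'   the sample's community that the model accounts for.
#' @export
setClass("CommunityModel",
  contains = "MetabolicModel",
  representation(taxa = "character", weights = "numeric",
                 coverage = "numeric")
)

setValidity("CommunityModel", function(object) {
  if (length(object@taxa) != length(object@weights))
    return("taxa and weights lengths differ")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("weights must renormalize to 1")
  if (length(object@coverage) != 1L || object@coverage < 0 ||
      object@coverage > 1 + 1e-9)
    return("coverage must be a single value in [0, 1]")
  TRUE
})

#' FluxSolution: result of a flux balance analysis solve
#'
#' @slot status `"optimal"`, `"infeasible"` or `"unbounded"`.
#' @slot fluxes named numeric vector of reaction fluxes (empty unless
#'   optimal).
#' @slot objective objective value at the optimum (`NA` otherwise).
#' @slot tolerance solver feasibility tolerance used for the steady-state
#'   and bound checks.
#' @export
setClass("FluxSolution",
  representation(status = "character", fluxes = "numeric",
                 objective = "numeric", tolerance = "numeric")
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  TRUE
})
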