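#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: taxon identity,
#' stoichiometric content, abundance values and flux solutions are read
#' through these rather than through direct slot access.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The corresponding slot content; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxonId", function(x) standardGeneric("taxonId"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("genusIds", function(x) standardGeneric("genusIds"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("memberWeights", function(x) standardGeneric("memberWeights"))

#' @rdname accessors
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' Normalize an abundance table to per-sample relative abundances
#'
#' @param x an [AbundanceTable-class].
#' @return An `AbundanceTable` whose columns (samples) each sum to one.
#' @export
setGeneric("toRelative", function(x) standardGeneric("toRelative"))
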