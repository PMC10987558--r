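#' Construct a per-taxon metabolic reconstruction
#'
#' @param taxonId single taxon (genus) identifier.
#' @param metabolites data.frame with columns `id` and `compartment`
#'   (`"internal"` or `"extracellular"`).
#' @param reactions data.frame with columns `id`, `stoich` (list column of
#'   named numeric vectors), `lb`, `ub`, `exchange`, `objective`.
#' @return a validated [MetabolicReconstruction-class].
#' @export
metabolicReconstruction <- function(taxonId, metabolites, reactions) {
  reactions$stoich <- lapply(reactions$stoich, function(s)
    stats::setNames(as.numeric(s), names(s)))
  obj <- new("MetabolicReconstruction", taxonId = taxonId,
             metabolites = as.data.frame(metabolites),
             reactions = as.data.frame(reactions))
  validObject(obj)
  obj
}

#' @rdname accessors
#' @export
setMethod("taxonId", "MetabolicReconstruction", function(x) x@taxonId)

#' @rdname accessors
#' @export
setMethod("reactions", "MetabolicModel", function(x) x@reactions)

#' @rdname accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)

setMethod("show", "MetabolicReconstruction", function(object) {
  cat(sprintf("MetabolicReconstruction '%s': %d metabolites, %d reactions (%d exchange)\n",
              object@taxonId, nrow(object@metabolites),
              nrow(object@reactions), sum(object@reactions$exchange)))
})

#' A minimal capacity-limited chain model
#'
#' Fixture used in documentation and tests: uptake of metabolite A (bounded
#' at 10 units), conversion A -> B, export of B, maximizing the export. The
#' optimum is 10, B is secreted at +10 and A consumed at -10.
#'
#' @return a [MetabolicReconstruction-class].
#' @export
chainModel <- function() {
  metabolicReconstruction(
    taxonId = "chain",
    metabolites = data.frame(id = c("A_e", "B_e"),
                             compartment = "extracellular"),
    reactions = data.frame(
      id = c("EX_A", "CONV", "EX_B"),
      stoich = I(list(c(A_e = -1), c(A_e = -1, B_e = 1), c(B_e = -1))),
      lb = c(-10, 0, 0), ub = c(0, 1000, 1000),
      exchange = c(TRUE, FALSE, TRUE),
      objective = c(0, 0, 1)))
}

modelToList <- function(model) {
  rxn <- model@reactions
  list(
    taxon_id = if (is(model, "MetabolicReconstruction")) model@taxonId
               else NA_character_,
    metabolites = lapply(seq_len(nrow(model@metabolites)), function(i)
      list(id = model@metabolites$id[i],
           compartment = model@metabolites$compartment[i])),
    reactions = lapply(seq_len(nrow(rxn)), function(i)
      list(id = rxn$id[i], stoich = as.list(rxn$stoich[[i]]),
           lb = rxn$lb[i], ub = rxn$ub[i],
           exchange = rxn$exchange[i], objective = rxn$objective[i])))
}

#' Write / read a metabolic reconstruction as JSON
#'
#' The dialect is `{taxon_id, metabolites: [{id, compartment}], reactions:
#' [{id, stoich: {met: coef}, lb, ub, exchange, objective}]}`. A read-back
#' model is identical to the written one up to JSON key order. Schema
#' violations raise errors naming the offending JSON path.
#'
#' @param model a [MetabolicReconstruction-class].
#' @param path file path.
#' @return `readModel` returns the validated reconstruction; `writeModel`
#'   returns `path` invisibly.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "MetabolicReconstruction"))
  jsonlite::write_json(modelToList(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

jsonField <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop(sprintf("model JSON missing '%s' at %s", field, where),
         call. = FALSE)
  x[[field]]
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  taxon <- jsonField(j, "taxon_id", "$")
  mets <- jsonField(j, "metabolites", "$")
  met <- data.frame(
    id = vapply(seq_along(mets), function(i)
      as.character(jsonField(mets[[i]], "id",
                             sprintf("$.metabolites[%d]", i))), ""),
    compartment = vapply(seq_along(mets), function(i)
      as.character(jsonField(mets[[i]], "compartment",
                             sprintf("$.metabolites[%d]", i))), ""),
    stringsAsFactors = FALSE)
  rx <- jsonField(j, "reactions", "$")
  rxn <- data.frame(
    id = vapply(seq_along(rx), function(i)
      as.character(jsonField(rx[[i]], "id",
                             sprintf("$.reactions[%d]", i))), ""),
    lb = vapply(seq_along(rx), function(i)
      as.numeric(jsonField(rx[[i]], "lb",
                           sprintf("$.reactions[%d]", i))), 0),
    ub = vapply(seq_along(rx), function(i)
      as.numeric(jsonField(rx[[i]], "ub",
                           sprintf("$.reactions[%d]", i))), 0),
    exchange = vapply(seq_along(rx), function(i)
      as.logical(jsonField(rx[[i]], "exchange",
                           sprintf("$.reactions[%d]", i))), NA),
    objective = vapply(seq_along(rx), function(i)
      as.numeric(jsonField(rx[[i]], "objective",
                           sprintf("$.reactions[%d]", i))), 0),
    stringsAsFactors = FALSE)
  rxn$stoich <- I(lapply(seq_along(rx), function(i) {
    s <- jsonField(rx[[i]], "stoich", sprintf("$.reactions[%d]", i))
    stats::setNames(vapply(s, as.numeric, 0), names(s))
  }))
  tryCatch(metabolicReconstruction(taxon, met, rxn), error = function(e)
    stop(sprintf("invalid model in '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
}

#' Read a directory of model JSON files as a model library
#'
#' @param dir directory containing one `<taxon>.json` per reconstruction.
#' @return named list of [MetabolicReconstruction-class], keyed by taxon id.
#' @export
readModelLibrary <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no model JSON files in ", dir)
  models <- lapply(files, readModel)
  stats::setNames(models, vapply(models, taxonId, ""))
}

#' Write a model library to a directory, one JSON file per taxon
#'
#' @param models named list of [MetabolicReconstruction-class].
#' @param dir output directory (created if absent).
#' @return `dir` invisibly.
#' @export
writeModelLibrary <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in models)
    writeModel(m, file.path(dir, paste0(taxonId(m), ".json")))
  invisible(dir)
}
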