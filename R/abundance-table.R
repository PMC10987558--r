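#' Construct an AbundanceTable
#'
#' @param counts numeric matrix, genera in rows and samples in columns, with
#'   dimnames. Values are read counts or proportions; all non-negative.
#' @param sampleData `data.frame` (or DataFrame) of per-sample metadata with
#'   one row per column of `counts`. Recognized columns: `subject_id`,
#'   `group`, `compartment`, `age`, `sex`, `cohort`. May be `NULL`.
#' @param normalized logical; set `TRUE` when columns are relative abundances
#'   summing to one.
#' @return An [AbundanceTable-class].
#' @examples
#' m <- matrix(c(2, 2, 0, 1, 3, 6), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' at <- abundanceTable(m)
#' toRelative(at)
#' @export
abundanceTable <- function(counts, sampleData = NULL, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(sampleData)) {
    sampleData <- S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    sampleData <- S4Vectors::DataFrame(sampleData)
    if (nrow(sampleData) != ncol(counts))
      stop("sampleData must have one row per sample (column of counts)")
    rownames(sampleData) <- colnames(counts)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = counts), colData = sampleData)
  new("AbundanceTable", se, normalized = normalized)
}

#' @rdname accessors
#' @export
setMethod("abundances", "AbundanceTable", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @rdname accessors
#' @export
setMethod("isNormalized", "AbundanceTable", function(x) x@normalized)

#' @rdname accessors
#' @export
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("genusIds", "AbundanceTable", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleData", "AbundanceTable", function(x)
  SummarizedExperiment::colData(x))

#' @describeIn toRelative Column-normalize counts to proportions. Samples
#'   with an all-zero column are rejected by name; an already-normalized
#'   table is returned unchanged (idempotent).
#' @export
setMethod("toRelative", "AbundanceTable", function(x) {
  if (isNormalized(x)) return(x)
  a <- abundances(x)
  cs <- colSums(a)
  if (any(cs <= 0)) {
    bad <- colnames(a)[cs <= 0]
    stop("cannot normalize all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  out <- sweep(a, 2, cs, "/")
  abundanceTable(out, sampleData = sampleData(x), normalized = TRUE)
})

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d genera x %d samples (%s)\n",
              nrow(object), ncol(object),
              if (object@normalized) "relative abundances" else "counts"))
  cd <- SummarizedExperiment::colData(object)
  if (ncol(cd)) cat("sample metadata:", paste(names(cd), collapse = ", "),
                    "\n")
})

# Validated metadata extraction used by group-comparison operations.
groupLabels <- function(table, column = "group") {
  cd <- sampleData(table)
  if (!column %in% names(cd))
    stop(sprintf("sample metadata column '%s' is missing", column))
  labs <- as.character(cd[[column]])
  names(labs) <- sampleIds(table)
  labs
}
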