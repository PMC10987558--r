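#' Read and write genus abundance tables as TSV
#'
#' The on-disk orientation follows common practice for genus tables: rows
#' are samples, columns are genera, with a header row of genus ids and a
#' first column of sample ids. In memory the table is transposed into the
#' Bioconductor genera-by-samples orientation. Duplicate ids, ragged rows
#' and negative values are rejected at load time with the offending
#' row/column named.
#'
#' @param path TSV file path.
#' @param metadata optional per-sample metadata `data.frame` to attach
#'   (see [readMetadata()]).
#' @param normalized whether stored values are relative abundances.
#' @return `readAbundance` returns an [AbundanceTable-class];
#'   `writeAbundance` returns `path` invisibly.
#' @export
readAbundance <- function(path, metadata = NULL, normalized = FALSE) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("abundance TSV needs sample ids plus >= 1 genus")
  sampleIds <- as.character(raw[[1]])
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(vals)))
    stop("duplicate genus ids in header")
  if (!is.numeric(vals)) stop("non-numeric abundance values")
  if (anyNA(vals)) stop("missing abundance values")
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at sample '%s', genus '%s'",
                 sampleIds[neg[1, 1]], colnames(vals)[neg[1, 2]]))
  rownames(vals) <- sampleIds
  if (!is.null(metadata)) {
    metadata <- metadata[match(sampleIds, metadata$sample_id), ,
                         drop = FALSE]
    if (anyNA(metadata$sample_id))
      stop("metadata missing for some samples")
  }
  abundanceTable(t(vals), sampleData = metadata, normalized = normalized)
}

#' @rdname readAbundance
#' @param table an [AbundanceTable-class] to write.
#' @export
writeAbundance <- function(table, path) {
  a <- t(abundances(table))
  df <- data.frame(sample_id = rownames(a), a, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata TSV
#'
#' Columns: `sample_id`, `subject_id`, `group`, `compartment`, `age`,
#' `sex`, `cohort`; `sample_id` must be unique.
#'
#' @param path TSV file path.
#' @return `readMetadata` returns a validated `data.frame`.
#' @export
readMetadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "group", "compartment", "age",
            "sex", "cohort")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  md
}

#' @rdname readMetadata
#' @param metadata metadata `data.frame` to write.
#' @export
writeMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
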