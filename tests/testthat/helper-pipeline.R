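# Write a complete small synthetic study (training + validation cohorts +
# model library) to disk, as runPipeline expects to find it.
writePipelineFixture <- function(dir, nPerGroup = 6, nGenera = 10,
                                 seed = 101) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  planted <- data.frame(genus = c("g002", "g004"),
                        direction = c("up", "down"), fold = c(3, 3))
  spec <- cohortSpec(nPerGroup = nPerGroup, nGenera = nGenera,
                     plantedGenera = planted, dispersion = 150,
                     readDepth = 5e3, seed = seed)
  train <- generateCohort(spec)
  vspec <- cohortSpec(nPerGroup = nPerGroup, nGenera = nGenera,
                      dispersion = 150, readDepth = 5e3, seed = seed + 1)
  valid <- generateValidationCohort(vspec, train$truth, shift = 0.5)

  taxa <- sprintf("g%03d", seq_len(nGenera))
  sm <- data.frame(taxon = taxa,
                   metabolite = sprintf("m%02d_e", seq_len(nGenera)),
                   mode = "secrete", stringsAsFactors = FALSE)
  lib <- generateModelLibrary(modelLibrarySpec(
    taxa = taxa, nExtracellularMetabolites = nGenera,
    signatureMap = sm, seed = seed + 2))

  paths <- list(
    abundance = file.path(dir, "abundance.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    validationAbundance = file.path(dir, "validation_abundance.tsv"),
    validationMetadata = file.path(dir, "validation_metadata.tsv"),
    models = file.path(dir, "models"))
  writeAbundance(train$table, paths$abundance)
  writeMetadata(as.data.frame(sampleData(train$table)), paths$metadata)
  writeAbundance(valid$table, paths$validationAbundance)
  writeMetadata(as.data.frame(sampleData(valid$table)),
                paths$validationMetadata)
  writeModelLibrary(lib, paths$models)
  paths$truth <- train$truth
  paths
}
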