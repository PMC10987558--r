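#' Pipeline configuration
#'
#' Collects every path, threshold, permutation count and seed the full
#' analysis needs, with fail-fast validation; the configuration
#' round-trips losslessly through JSON. A seed is mandatory — randomized
#' stages never fall back to a silent default.
#'
#' @param abundance,metadata paths to the training abundance and metadata
#'   TSVs.
#' @param models path to the model-library directory (JSON files).
#' @param out output directory.
#' @param validationAbundance,validationMetadata optional paths for an
#'   independent validation cohort.
#' @param caseGroup,controlGroup compared group labels.
#' @param taxonThreshold taxon-selection cutoff (default 0.01).
#' @param pThreshold,fdrThreshold significance filter (defaults 0.05, 0.1).
#' @param coverageFloor minimum acceptable per-sample model coverage
#'   (default 0.5; lower coverage flags the sample).
#' @param nPerm permutation count for PERMANOVA, differential abundance and
#'   bioavailability FDR (default 1000).
#' @param seed master integer seed, split into per-stage substreams.
#' @param medianSummary use the median instead of the mean group summary in
#'   the bioavailability index.
#' @param batchCorrection mean-center flux features per cohort before
#'   validation (default `TRUE` when a validation cohort is given).
#' @param cailliez apply the Cailliez correction in PCoA.
#' @param runTsne compute a t-SNE embedding of the flux profiles (needs
#'   n > 3 * perplexity; default `FALSE`).
#' @return a validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(abundance, metadata, models, out,
                           validationAbundance = NULL,
                           validationMetadata = NULL,
                           caseGroup = "MS", controlGroup = "HV",
                           taxonThreshold = 0.01, pThreshold = 0.05,
                           fdrThreshold = 0.1, coverageFloor = 0.5,
                           nPerm = 1000, seed, medianSummary = FALSE,
                           batchCorrection = TRUE, cailliez = FALSE,
                           runTsne = FALSE) {
  if (missing(seed)) stop("a seed is required")
  assertScalarNumber(seed, "seed", integer = TRUE)
  assertScalarNumber(taxonThreshold, "taxonThreshold", 0, 1)
  assertScalarNumber(pThreshold, "pThreshold", 0, 1)
  assertScalarNumber(fdrThreshold, "fdrThreshold", 0, 1)
  assertScalarNumber(coverageFloor, "coverageFloor", 0, 1)
  assertScalarNumber(nPerm, "nPerm", lower = 1, integer = TRUE)
  for (p in c(abundance, metadata, models, validationAbundance,
              validationMetadata))
    if (!file.exists(p)) stop("path does not exist: ", p)
  structure(list(abundance = abundance, metadata = metadata,
                 models = models, out = out,
                 validationAbundance = validationAbundance,
                 validationMetadata = validationMetadata,
                 caseGroup = caseGroup, controlGroup = controlGroup,
                 taxonThreshold = taxonThreshold,
                 pThreshold = pThreshold, fdrThreshold = fdrThreshold,
                 coverageFloor = coverageFloor, nPerm = as.integer(nPerm),
                 seed = as.integer(seed), medianSummary = medianSummary,
                 batchCorrection = batchCorrection, cailliez = cailliez,
                 runTsne = runTsne), class = "pipelineConfig")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [pipelineConfig()].
#' @param path JSON file path.
#' @return `readPipelineConfig` returns the restored configuration.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, j)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ecology (relative abundances, alpha diversity,
#' Bray-Curtis, PERMANOVA, differential abundance), community flux balance
#' analysis (taxon selection, per-individual community models, boundary
#' fluxes, bioavailability index), and discrimination (stepwise-AIC
#' logistic classifier on the flux profiles with ROC, plus frozen-model
#' validation on an independent cohort when configured). Every stage
#' output is written under `config$out` together with a provenance record;
#' rerunning with an identical configuration and seed reproduces the
#' deterministic outputs bit-identically (the provenance file carries the
#' only timestamps).
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) a list with all stage results and the provenance
#'   record.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  prov <- list(config = unclass(config),
               package = as.character(utils::packageVersion("fluxbiome")),
               seed = config$seed, warnings = character(0), stages = list())
  t0 <- proc.time()[["elapsed"]]
  stageTime <- function() proc.time()[["elapsed"]] - t0
  stageErr <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- ecology -----------------------------------------------------------
  res <- list()
  stageErr("ecology", {
    md <- readMetadata(config$metadata)
    tab <- readAbundance(config$abundance, metadata = md)
    rel <- toRelative(tab)
    div <- shannonDiversity(rel)
    writeTsv(div, file.path(config$out, "diversity.tsv"))
    D <- brayCurtis(rel)
    perma <- permanova(D, groupLabels(rel), nPerm = config$nPerm,
                       seed = substreamSeed(config$seed, "permanova"))
    ord <- pcoa(D, k = 2, cailliez = config$cailliez)
    da <- diffAbundance(rel, case = config$caseGroup,
                        control = config$controlGroup,
                        nPerm = config$nPerm,
                        seed = substreamSeed(config$seed, "diffabund"))
    writeTsv(da, file.path(config$out, "diff_abundance.tsv"))
    jsonlite::write_json(
      list(permanova = perma,
           pcoaEigenvalues = ord$eigenvalues),
      file.path(config$out, "ecology_summary.json"),
      auto_unbox = TRUE, digits = NA)
    res$table <- rel
    res$diversity <- div
    res$permanova <- perma
    res$pcoa <- ord
    res$diffAbundance <- da
  })
  prov$stages$ecology <- stageTime()

  # --- community FBA -----------------------------------------------------
  stageErr("community_fba", {
    models <- readModelLibrary(config$models)
    cf <- cohortFluxes(res$table, models,
                       threshold = config$taxonThreshold,
                       coverageFloor = config$coverageFloor)
    if (any(cf$flagged)) {
      w <- sprintf("%d sample(s) below coverage floor %.2f: %s",
                   sum(cf$flagged), config$coverageFloor,
                   paste(names(which(cf$flagged)), collapse = ", "))
      warning(w, call. = FALSE)
      prov$warnings <- c(prov$warnings, w)
    }
    bio <- bioavailability(
      cf$fluxes, groupLabels(res$table), case = config$caseGroup,
      control = config$controlGroup, nPerm = config$nPerm,
      seed = substreamSeed(config$seed, "bioavailability"),
      summary = if (config$medianSummary) "median" else "mean",
      pThreshold = config$pThreshold, fdrThreshold = config$fdrThreshold)
    writeTsv(data.frame(sample_id = rownames(cf$fluxes), cf$fluxes,
                        check.names = FALSE),
             file.path(config$out, "fluxes.tsv"))
    writeTsv(bio, file.path(config$out, "bioavailability.tsv"))
    jsonlite::write_json(
      list(coverage = as.list(cf$coverage),
           flagged = as.list(cf$flagged),
           selectedTaxa = cf$selectedTaxa,
           solver = "bounded-variable simplex (parsimonious)",
           pseudoFlux = 1e-6),
      file.path(config$out, "coverage_report.json"),
      auto_unbox = TRUE, digits = NA)
    res$fluxes <- cf
    res$bioavailability <- bio
  })
  prov$stages$community_fba <- stageTime()

  # --- discriminate ------------------------------------------------------
  stageErr("discriminate", {
    y <- groupLabels(res$table)
    keep <- y %in% c(config$caseGroup, config$controlGroup)
    Xtr <- res$fluxes$fluxes[keep, , drop = FALSE]
    ytr <- y[keep]
    hasValidation <- !is.null(config$validationAbundance)
    if (hasValidation) {
      vmd <- readMetadata(config$validationMetadata)
      vtab <- toRelative(readAbundance(config$validationAbundance,
                                       metadata = vmd))
      vmodels <- readModelLibrary(config$models)
      vcf <- cohortFluxes(vtab, vmodels,
                          threshold = config$taxonThreshold,
                          coverageFloor = config$coverageFloor)
      shared <- intersect(colnames(Xtr), colnames(vcf$fluxes))
      Xva <- vcf$fluxes[, shared, drop = FALSE]
      Xtr2 <- Xtr[, shared, drop = FALSE]
      if (config$batchCorrection) {
        bc <- batchCorrect(Xtr2, Xva)
        Xtr2 <- bc$Xa
        Xva <- bc$Xb
      }
      model <- stepwiseAIC(Xtr2, ytr, positive = config$caseGroup)
      yva <- vmd$group[match(rownames(Xva), vmd$sample_id)]
      val <- validateExternal(model, Xva, yva)
    } else {
      model <- stepwiseAIC(Xtr, ytr, positive = config$caseGroup)
      val <- NULL
    }
    modelOut <- list(features = model$features,
                     intercept = model$intercept,
                     coefficients = as.list(model$coefficients),
                     waldP = as.list(model$waldP),
                     aic = model$aic, logLik = model$logLik,
                     separation = model$separation,
                     threshold = model$threshold,
                     standardization = model$standardization,
                     trainingAuc = model$roc$auc,
                     validationAuc = if (!is.null(val)) val$roc$auc else NULL,
                     validationSpecificity =
                       if (!is.null(val)) val$specificity else NULL)
    jsonlite::write_json(modelOut, file.path(config$out, "model.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeTsv(data.frame(fpr = model$roc$fpr, tpr = model$roc$tpr),
             file.path(config$out, "roc_training.tsv"))
    if (!is.null(val))
      writeTsv(data.frame(fpr = val$roc$fpr, tpr = val$roc$tpr),
               file.path(config$out, "roc_validation.tsv"))
    if (config$runTsne) {
      emb <- tsneEmbed(Xtr, seed = substreamSeed(config$seed, "tsne"))
      writeTsv(data.frame(sample_id = rownames(emb$coordinates),
                          emb$coordinates),
               file.path(config$out, "tsne.tsv"))
      res$tsne <- emb
    }
    res$model <- model
    res$validation <- val
  })
  prov$stages$discriminate <- stageTime()

  prov$wallClock <- stageTime()
  prov$date <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(prov, file.path(config$out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  res$provenance <- prov
  invisible(res)
}
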