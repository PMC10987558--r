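# Z-score standardization with a reusable record, so validation cohorts can
# be transformed with frozen training parameters.
standardizeFeatures <- function(X, record = NULL) {
  X <- as.matrix(X)
  if (is.null(record)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0] <- 1
    record <- list(center = center, scale = scale)
  }
  Xz <- sweep(sweep(X[, names(record$center), drop = FALSE], 2,
                    record$center, "-"), 2, record$scale, "/")
  list(X = Xz, record = record)
}

asBinary <- function(y, positive = NULL) {
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("y must have exactly two classes")
  if (is.null(positive)) positive <- lev[2]
  list(y01 = as.integer(y == positive), positive = positive,
       negative = setdiff(lev, positive))
}

#' Maximum-likelihood logistic regression
#'
#' Fits a binomial GLM by iteratively reweighted least squares
#' ([stats::glm()]) and packages the result with its log-likelihood, AIC
#' (2k - 2 logLik, k counting the intercept), per-coefficient Wald p-values
#' and a complete-separation flag (raised when the IRLS does not converge or
#' fitted probabilities degenerate to 0/1, in which case coefficients are
#' not identified).
#'
#' @param X numeric samples x features matrix (may have zero columns for
#'   the intercept-only model).
#' @param y two-class labels.
#' @param positive label treated as the positive class (default: second
#'   level alphabetically).
#' @return an object of class `logisticModel`: list with `features`,
#'   `intercept`, `coefficients`, `logLik`, `aic`, `waldP`, `separation`,
#'   `positive`, `fitted`.
#' @export
logisticFit <- function(X, y, positive = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("features must be finite")
  b <- asBinary(y, positive)
  if (sum(b$y01) < 2 || sum(1 - b$y01) < 2)
    stop("each class needs at least 2 samples")
  df <- data.frame(.y = b$y01)
  if (ncol(X)) {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    df <- cbind(df, as.data.frame(X))
  }
  sep <- FALSE
  fml <- if (ncol(X)) .y ~ . else .y ~ 1
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) sep <- TRUE
  co <- summary(fit)$coefficients
  cf <- stats::coef(fit)
  structure(list(
    features = setdiff(names(cf), "(Intercept)"),
    intercept = unname(cf["(Intercept)"]),
    coefficients = cf[setdiff(names(cf), "(Intercept)")],
    logLik = as.numeric(stats::logLik(fit)),
    aic = fit$aic,
    waldP = co[, "Pr(>|z|)"],
    separation = sep,
    positive = b$positive,
    fitted = unname(stats::fitted(fit)),
    glm = fit), class = "logisticModel")
}

#' @export
print.logisticModel <- function(x, ...) {
  cat(sprintf("logisticModel: %d feature(s), AIC = %.3f, logLik = %.3f%s\n",
              length(x$features), x$aic, x$logLik,
              if (x$separation) " [separation: not identified]" else ""))
  if (length(x$features))
    cat("features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Stepwise-AIC logistic classifier
#'
#' Bidirectional stepwise variable selection minimizing Akaike's
#' information criterion, starting from the intercept-only model
#' ([stats::step()] over a binomial GLM). Features are z-scored first and
#' the standardization record is frozen into the model for external
#' validation; the training ROC and its Youden-J operating point are stored
#' as well. The accepted-step AIC trace is strictly decreasing by
#' construction and is kept in the result.
#'
#' @param X samples x features matrix.
#' @param y two-class labels.
#' @param positive positive-class label.
#' @param maxSteps cap on accepted steps (default 1000).
#' @param standardize z-score features before selection (default `TRUE`).
#' @return a `logisticModel` with additional elements `standardization`,
#'   `trace` (data.frame of accepted steps and AIC), `roc` (training
#'   [rocAuc()] result) and `threshold` (Youden-J probability cutoff).
#' @export
stepwiseAIC <- function(X, y, positive = NULL, maxSteps = 1000,
                        standardize = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  std <- if (standardize) standardizeFeatures(X)
         else list(X = X, record = NULL)
  b <- asBinary(y, positive)
  df <- cbind(data.frame(.y = b$y01), as.data.frame(std$X))
  null <- stats::glm(.y ~ 1, data = df, family = stats::binomial())
  scope <- stats::as.formula(paste("~", paste(sprintf("`%s`",
                                                      colnames(X)),
                                              collapse = " + ")))
  sel <- suppressWarnings(
    stats::step(null, scope = list(lower = ~1, upper = scope),
                direction = "both", trace = 0, steps = maxSteps))
  cf <- stats::coef(sel)
  feats <- gsub("`", "", setdiff(names(cf), "(Intercept)"))
  model <- logisticFit(std$X[, feats, drop = FALSE], y, positive = positive)
  model$standardization <- std$record
  model$trace <- data.frame(step = sel$anova$Step, aic = sel$anova$AIC,
                            stringsAsFactors = FALSE)
  scores <- model$fitted
  model$roc <- rocAuc(scores, y, positive = b$positive)
  j <- which.max(model$roc$tpr - model$roc$fpr)
  model$threshold <- model$roc$thresholds[j]
  model
}

#' ROC curve and AUC
#'
#' Receiver operating characteristic of a score against two-class labels,
#' computed with [pROC::roc()] (higher scores favour the positive class;
#' ties advance sensitivity and specificity simultaneously). The AUC equals
#' the trapezoidal area, i.e. the concordance probability with ties counted
#' half.
#'
#' @param scores numeric scores.
#' @param y two-class labels.
#' @param positive positive-class label.
#' @return an object of class `rocResult`: list with `fpr`, `tpr`,
#'   `thresholds`, `auc`, `positive`.
#' @export
rocAuc <- function(scores, y, positive = NULL) {
  b <- asBinary(y, positive)
  if (length(unique(b$y01)) != 2) stop("both classes must be present")
  r <- pROC::roc(response = b$y01, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  structure(list(fpr = (1 - r$specificities)[ord],
                 tpr = r$sensitivities[ord],
                 thresholds = r$thresholds[ord],
                 auc = as.numeric(pROC::auc(r)),
                 positive = b$positive), class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("rocResult: AUC = %.3f (positive class '%s', %d points)\n",
              x$auc, x$positive, length(x$fpr)))
  invisible(x)
}

#' Frozen-model external validation
#'
#' Applies a trained `logisticModel` to an independent cohort without any
#' refitting: the training standardization is applied to the new features,
#' scores come from the frozen coefficients, and the ROC/AUC is computed on
#' the new labels. Sensitivity and specificity at the training-chosen
#' Youden-J operating point are reported alongside.
#'
#' @param model a `logisticModel` from [stepwiseAIC()] (or [logisticFit()]
#'   with a standardization record attached).
#' @param X samples x features matrix of the validation cohort; must
#'   contain every selected feature.
#' @param y validation labels.
#' @return list with `roc` (an `rocResult`), `scores`, `sensitivity`,
#'   `specificity` at the frozen threshold.
#' @export
validateExternal <- function(model, X, y) {
  stopifnot(inherits(model, "logisticModel"))
  X <- as.matrix(X)
  missingFeat <- setdiff(model$features, colnames(X))
  if (length(missingFeat))
    stop("validation features missing: ", paste(missingFeat,
                                                collapse = ", "))
  if (!is.null(model$standardization)) {
    rec <- model$standardization
    rec$center <- rec$center[model$features]
    rec$scale <- rec$scale[model$features]
    Xz <- standardizeFeatures(X[, model$features, drop = FALSE], rec)$X
  } else {
    Xz <- X[, model$features, drop = FALSE]
  }
  eta <- model$intercept +
    if (length(model$features))
      as.vector(Xz %*% model$coefficients[model$features]) else 0
  scores <- stats::plogis(eta)
  roc <- rocAuc(scores, y, positive = model$positive)
  b <- asBinary(y, model$positive)
  thr <- if (!is.null(model$threshold)) model$threshold else 0.5
  pred <- as.integer(scores >= thr)
  list(roc = roc, scores = scores,
       sensitivity = sum(pred == 1 & b$y01 == 1) / sum(b$y01 == 1),
       specificity = sum(pred == 0 & b$y01 == 0) / sum(b$y01 == 0))
}

#' Per-cohort mean-centering batch correction
#'
#' Removes per-feature location offsets between two cohorts by centering
#' each cohort's features at zero. After correction each cohort's
#' per-feature mean is 0 within 1e-12; already-centered cohorts pass
#' through unchanged.
#'
#' @param Xa,Xb samples x features matrices sharing feature names.
#' @return list with corrected `Xa`, `Xb` and `method = "mean-centering"`.
#' @export
batchCorrect <- function(Xa, Xb) {
  Xa <- as.matrix(Xa)
  Xb <- as.matrix(Xb)
  shared <- intersect(colnames(Xa), colnames(Xb))
  if (!length(shared)) stop("cohorts share no features")
  Xa <- Xa[, shared, drop = FALSE]
  Xb <- Xb[, shared, drop = FALSE]
  list(Xa = sweep(Xa, 2, colMeans(Xa), "-"),
       Xb = sweep(Xb, 2, colMeans(Xb), "-"),
       method = "mean-centering")
}

#' Two-dimensional t-SNE embedding of a feature matrix
#'
#' Exact t-distributed stochastic neighbour embedding ([Rtsne::Rtsne()]
#' with `theta = 0`): per-point Gaussian bandwidths matched to the
#' perplexity, symmetrized affinities, Student-t low-dimensional kernel and
#' early exaggeration. Seeded and reporting the final KL divergence.
#'
#' @param X samples x features matrix (n > 3 * perplexity).
#' @param perplexity Gaussian-neighbourhood size (default 10, suited to
#'   small cohorts).
#' @param nIter gradient-descent iterations (default 1000).
#' @param seed integer seed (mandatory).
#' @return list with `coordinates` (n x 2), `kl` (final KL divergence),
#'   `klTrace`, `perplexity`, `nIter`, `seed`.
#' @export
tsneEmbed <- function(X, perplexity = 10, nIter = 1000, seed) {
  X <- as.matrix(X)
  if (missing(seed)) stop("a seed is required")
  if (nrow(X) <= 3 * perplexity)
    stop(sprintf("perplexity %g infeasible for n = %d (need n > 3*perplexity)",
                 perplexity, nrow(X)))
  fit <- withSeed(seed,
    Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, theta = 0,
                 max_iter = nIter, check_duplicates = FALSE, pca = FALSE,
                 verbose = FALSE))
  coords <- fit$Y
  rownames(coords) <- rownames(X)
  colnames(coords) <- c("tsne1", "tsne2")
  list(coordinates = coords, kl = fit$itercosts[length(fit$itercosts)],
       klTrace = fit$itercosts, perplexity = perplexity, nIter = nIter,
       seed = seed)
}
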