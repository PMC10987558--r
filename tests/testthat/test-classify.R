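test_that("the null logistic model has its closed-form likelihood", {
  y <- rep(c("HV", "MS"), each = 10)
  fit <- logisticFit(matrix(numeric(0), 20, 0), y)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$logLik, 20 * log(0.5), tolerance = 1e-8)
  expect_equal(fit$aic, 2 - 2 * 20 * log(0.5), tolerance = 1e-8)
})

test_that("complete separation is detected and flagged", {
  x <- matrix(c(-(10:1), 1:10), ncol = 1)
  colnames(x) <- "f"
  y <- rep(c("HV", "MS"), each = 10)
  fit <- logisticFit(x, y)
  expect_true(fit$separation)
})

test_that("the IRLS optimum matches an independent optimizer", {
  set.seed(12)
  n <- 60
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  eta <- 0.5 + X %*% c(1, -0.7)
  y <- ifelse(runif(n) < plogis(eta), "MS", "HV")
  fit <- logisticFit(X, y, positive = "MS")
  nll <- function(th) {
    e <- th[1] + X %*% th[2:3]
    -sum(ifelse(y == "MS", plogis(e, log.p = TRUE),
                plogis(-e, log.p = TRUE)))
  }
  ref <- optim(c(0, 0, 0), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$logLik, -ref$value, tolerance = 1e-4)
})

test_that("stepwise selection has a strictly decreasing AIC trace", {
  set.seed(9)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  eta <- X[, 1] * 2 - X[, 2] * 1.5
  y <- ifelse(runif(n) < plogis(eta), "MS", "HV")
  model <- stepwiseAIC(X, y, positive = "MS")
  expect_true(all(diff(model$trace$aic) < 0))
  expect_true(all(c("f1", "f2") %in% model$features))
  expect_s3_class(model$roc, "rocResult")
  expect_true(model$threshold >= 0 && model$threshold <= 1)
})

test_that("ROC/AUC matches brute-force pair counting", {
  y <- c("HV", "HV", "HV", "HV", "MS", "MS", "MS", "MS")
  s <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.55, 0.55, 0.9)
  res <- rocAuc(s, y, positive = "MS")
  pos <- s[y == "MS"]
  neg <- s[y == "HV"]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  expect_equal(res$auc, conc / (length(pos) * length(neg)),
               tolerance = 1e-12)

  expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12),
                      rep(c("HV", "MS"), each = 3))$auc, 1)
  expect_equal(rocAuc(rep(1, 6), rep(c("HV", "MS"), each = 3))$auc, 0.5)

  # AUC is invariant under strictly monotone score transforms
  set.seed(2)
  sc <- rnorm(30)
  yy <- sample(rep(c("HV", "MS"), 15))
  expect_equal(rocAuc(sc, yy)$auc, rocAuc(exp(sc), yy)$auc)
  expect_error(rocAuc(sc, rep("MS", 30)), "two classes")
})

test_that("external validation freezes the trained model", {
  set.seed(30)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  eta <- X[, 1] * 2 + X[, 2] * 1.5
  y <- ifelse(runif(n) < plogis(eta), "MS", "HV")
  model <- stepwiseAIC(X, y, positive = "MS")
  coefBefore <- model$coefficients

  # validating on the training set reproduces the training AUC
  val <- validateExternal(model, X, y)
  expect_equal(val$roc$auc, model$roc$auc, tolerance = 1e-12)
  expect_identical(model$coefficients, coefBefore)

  # shuffled labels transfer at chance level on average
  aucs <- vapply(1:20, function(i)
    validateExternal(model, X, sample(y))$roc$auc, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)

  expect_error(validateExternal(model,
    X[, setdiff(colnames(X), model$features[1]), drop = FALSE], y),
    "missing")
})

test_that("batch correction centers cohorts exactly and idempotently", {
  set.seed(3)
  Xa <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  Xb <- sweep(matrix(rnorm(40), 10, 4,
                     dimnames = list(NULL, paste0("f", 1:4))),
              2, c(5, -3, 2, 0), "+")
  bc <- batchCorrect(Xa, Xb)
  expect_lt(max(abs(colMeans(bc$Xa))), 1e-12)
  expect_lt(max(abs(colMeans(bc$Xb))), 1e-12)
  # already-centered input passes through unchanged
  bc2 <- batchCorrect(bc$Xa, bc$Xb)
  expect_equal(bc2$Xa, bc$Xa, tolerance = 1e-12)
  # a constant offset is removed exactly
  bc3 <- batchCorrect(bc$Xa, sweep(bc$Xa, 2, 7, "+"))
  expect_equal(bc3$Xb, bc$Xa, tolerance = 1e-12)
  expect_error(batchCorrect(Xa, matrix(1, 2, 2,
                                       dimnames = list(NULL, c("z1", "z2")))),
               "no features")
})

test_that("t-SNE embeds structure reproducibly", {
  set.seed(5)
  X <- rbind(matrix(rnorm(30 * 4, 0), 30, 4),
             matrix(rnorm(30 * 4, 6), 30, 4))
  rownames(X) <- sprintf("s%02d", 1:60)
  emb <- tsneEmbed(X, perplexity = 10, nIter = 500, seed = 42)
  expect_equal(dim(emb$coordinates), c(60, 2))
  expect_true(is.finite(emb$kl) && emb$kl >= 0)
  # same seed reproduces the embedding
  emb2 <- tsneEmbed(X, perplexity = 10, nIter = 500, seed = 42)
  expect_identical(emb$coordinates, emb2$coordinates)
  # KL divergence does not increase over the reported trace tail
  tail <- emb$klTrace[ceiling(length(emb$klTrace) / 2):length(emb$klTrace)]
  expect_true(all(diff(tail) <= 1e-8))
  # two well-separated clusters stay separated in 2-D
  d1 <- emb$coordinates[1:30, ]
  d2 <- emb$coordinates[31:60, ]
  between <- sqrt(sum((colMeans(d1) - colMeans(d2))^2))
  within <- mean(c(apply(d1, 2, sd), apply(d2, 2, sd)))
  expect_gt(between, 2 * within)

  # duplicated points land (near-)coincident relative to the diameter
  Xd <- rbind(X, X[1, , drop = FALSE])
  rownames(Xd) <- c(rownames(X), "dup")
  embd <- tsneEmbed(Xd, perplexity = 10, nIter = 500, seed = 7)
  dd <- sqrt(sum((embd$coordinates["dup", ] -
                    embd$coordinates["s01", ])^2))
  diam <- max(dist(embd$coordinates))
  expect_lt(dd, 0.05 * diam)

  expect_error(tsneEmbed(X[1:10, ], perplexity = 10, seed = 1),
               "perplexity")
  expect_error(tsneEmbed(X, perplexity = 10), "seed")
})
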