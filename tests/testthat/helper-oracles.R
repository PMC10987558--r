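# Independent oracles and fixture builders used across the suite.

# Exhaustive vertex enumeration for  max c'v : S v = 0, lb <= v <= ub.
# Requires S to have full row rank. Every vertex has m basic variables
# (nonsingular basis) and n - m variables at a bound; enumerate all of them.
vertexEnumerate <- function(obj, S, lb, ub) {
  m <- nrow(S)
  n <- ncol(S)
  stopifnot(qr(S)$rank == m)
  best <- -Inf
  for (bset in utils::combn(n, m, simplify = FALSE)) {
    B <- S[, bset, drop = FALSE]
    if (abs(det(B)) < 1e-9) next
    nb <- setdiff(seq_len(n), bset)
    for (mask in 0:(2^length(nb) - 1)) {
      x <- numeric(n)
      for (k in seq_along(nb))
        x[nb[k]] <- if (bitwAnd(mask, bitwShiftL(1, k - 1)) > 0)
          ub[nb[k]] else lb[nb[k]]
      x[bset] <- solve(B, -S[, nb, drop = FALSE] %*% x[nb])
      if (all(x >= lb - 1e-8 & x <= ub + 1e-8))
        best <- max(best, sum(obj * x))
    }
  }
  best
}

# Random small but structurally valid reconstruction for oracle tests:
# a couple of extracellular metabolites with exchanges, random internal
# conversions, an objective on the last reaction. Full-row-rank S enforced.
randomToyModel <- function(seed) {
  set.seed(seed)
  repeat {
    nExt <- sample(1:2, 1)
    nInt <- sample(1:3, 1)
    mets <- data.frame(
      id = c(sprintf("e%d", seq_len(nExt)), sprintf("i%d", seq_len(nInt))),
      compartment = c(rep("extracellular", nExt), rep("internal", nInt)),
      stringsAsFactors = FALSE)
    nConv <- sample(2:5, 1)
    stoich <- c(
      lapply(seq_len(nExt), function(k) stats::setNames(-1,
                                                        sprintf("e%d", k))),
      lapply(seq_len(nConv), function(k) {
        nm <- sample(mets$id, sample(2:min(3, nrow(mets)), 1))
        stats::setNames(sample(c(-2, -1, 1, 2), length(nm), replace = TRUE),
                        nm)
      }))
    nRxn <- nExt + nConv
    if (nRxn > 8) next
    rxn <- data.frame(
      id = sprintf("r%d", seq_len(nRxn)),
      lb = c(runif(nExt, -10, -1), ifelse(runif(nConv) < 0.3,
                                          -runif(nConv, 0, 5), 0)),
      ub = runif(nRxn, 1, 10),
      exchange = c(rep(TRUE, nExt), rep(FALSE, nConv)),
      objective = c(rep(0, nRxn - 1), 1),
      stringsAsFactors = FALSE)
    rxn$stoich <- I(stoich)
    model <- try(metabolicReconstruction("toy", mets, rxn), silent = TRUE)
    if (inherits(model, "try-error")) next
    S <- fluxbiome:::stoichMatrix(model)
    if (qr(S)$rank < nrow(S)) next
    return(model)
  }
}

# Brute-force Bray-Curtis from the defining formula.
bruteBrayCurtis <- function(X) {  # X: samples x genera
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(abs(X[i, ] - X[j, ])) / sum(X[i, ] + X[j, ])
  D
}

# Brute-force PERMANOVA p by explicit enumeration over supplied label
# assignments, with an independently coded pseudo-F.
brutePseudoF <- function(D, labels) {
  n <- nrow(D)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + D[idx[a], idx[b]]^2
    ssw <- ssw + s / length(idx)
  }
  a <- length(unique(labels))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# A small standard library + cohort pairing used by several tests.
makeTestLibrary <- function(nTaxa = 6, seed = 5, modes = NULL) {
  taxa <- sprintf("g%03d", seq_len(nTaxa))
  sm <- data.frame(taxon = taxa,
                   metabolite = sprintf("m%02d_e", seq_len(nTaxa)),
                   mode = if (is.null(modes)) rep("secrete", nTaxa)
                          else modes,
                   stringsAsFactors = FALSE)
  generateModelLibrary(modelLibrarySpec(
    taxa = taxa, nExtracellularMetabolites = nTaxa,
    signatureMap = sm, seed = seed))
}
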