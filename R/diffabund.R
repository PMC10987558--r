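# Vectorized two-sided Wilcoxon rank-sum tests for one feature matrix
# (samples x features) and a two-group split. Exact distribution when the
# combined n is <= 20 and the feature has no ties; otherwise the normal
# approximation with tie correction and continuity correction. Ranks and tie
# corrections are computed once so label permutations are cheap.
rankSumPrepare <- function(X) {
  R <- apply(X, 2, rank)
  if (is.null(dim(R))) R <- matrix(R, ncol = ncol(X))
  n <- nrow(X)
  tieSum <- apply(X, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  list(R = R, n = n, tieSum = tieSum, hasTies = tieSum > 0)
}

rankSumTest <- function(prep, idx1) {
  n <- prep$n
  n1 <- length(idx1)
  n2 <- n - n1
  W <- colSums(prep$R[idx1, , drop = FALSE]) - n1 * (n1 + 1) / 2  # U stat
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - prep$tieSum / (n * (n - 1)))
  p <- numeric(length(W))
  exactOK <- !prep$hasTies & n <= 20
  if (any(exactOK)) {
    w <- W[exactOK]
    pl <- stats::pwilcox(w, n1, n2)
    pu <- 1 - stats::pwilcox(w - 1, n1, n2)
    p[exactOK] <- pmin(1, 2 * pmin(pl, pu))
  }
  if (any(!exactOK)) {
    w <- W[!exactOK]
    s <- sqrt(sigma2[!exactOK])
    z <- ifelse(s > 0, (w - mu - sign(w - mu) * 0.5) / s, 0)
    p[!exactOK] <- ifelse(s > 0, pmin(1, 2 * stats::pnorm(-abs(z))), 1)
  }
  list(W = W, p = p)
}

#' Permutation-based FDR (plug-in estimator)
#'
#' For each observed p-value, the estimated FDR at threshold p is the median
#' over label permutations of the number of null p-values at or below p,
#' divided by the observed number at or below p, clipped to \[0, 1\] and
#' monotonized so q is non-decreasing in p.
#'
#' @param pObs observed p-values (one per feature).
#' @param pPerm matrix of permutation-null p-values, features x permutations.
#' @return numeric q-values aligned with `pObs`.
#' @export
permutationFDR <- function(pObs, pPerm) {
  stopifnot(nrow(pPerm) == length(pObs))
  B <- ncol(pPerm)
  ord <- order(pObs)
  q <- numeric(length(pObs))
  # counts of null p <= threshold, per permutation
  for (i in seq_along(ord)) {
    g <- ord[i]
    thr <- pObs[g]
    V <- colSums(pPerm <= thr)
    R <- sum(pObs <= thr)
    q[g] <- min(1, stats::median(V) / max(1, R))
  }
  # monotonize: q non-decreasing in p (suffix minimum over increasing p)
  qs <- q[ord]
  qs <- rev(cummin(rev(qs)))
  q[ord] <- qs
  q
}

#' Differential abundance: Wilcoxon tests with permutation-based FDR
#'
#' Per-genus two-sided Wilcoxon rank-sum tests between two groups on a
#' normalized abundance table, corrected by the permutation-based FDR of
#' [permutationFDR()] with label permutations.
#'
#' @param table normalized [AbundanceTable-class].
#' @param case,control the two group labels to compare (from the `group`
#'   metadata column, or from `labels`).
#' @param labels optional explicit per-sample labels overriding the
#'   metadata.
#' @param nPerm number of label permutations for the FDR (default 1000).
#' @param seed integer seed (mandatory).
#' @return `data.frame`, one row per genus: `genus`, `meanCase`,
#'   `meanControl`, `W`, `p`, `q`, ordered as in the table.
#' @export
diffAbundance <- function(table, case, control, labels = NULL, nPerm = 1000,
                          seed) {
  stopifnot(is(table, "AbundanceTable"))
  if (!isNormalized(table))
    stop("diffAbundance expects a normalized table; see toRelative()")
  if (missing(seed)) stop("a seed is required")
  assertScalarNumber(nPerm, "nPerm", lower = 1, integer = TRUE)
  if (is.null(labels)) labels <- groupLabels(table)
  keep <- labels %in% c(case, control)
  X <- t(abundances(table))[keep, , drop = FALSE]
  labs <- labels[keep]
  n1 <- sum(labs == case)
  n2 <- sum(labs == control)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  prep <- rankSumPrepare(X)
  idx1 <- which(labs == case)
  obs <- rankSumTest(prep, idx1)
  pPerm <- withSeed(substreamSeed(seed, "diffabund"), {
    vapply(seq_len(nPerm), function(b) {
      rankSumTest(prep, sample(nrow(X), n1))$p
    }, numeric(ncol(X)))
  })
  if (is.null(dim(pPerm))) pPerm <- matrix(pPerm, nrow = ncol(X))
  q <- permutationFDR(obs$p, pPerm)
  data.frame(genus = colnames(X),
             meanCase = colMeans(X[labs == case, , drop = FALSE]),
             meanControl = colMeans(X[labs == control, , drop = FALSE]),
             W = obs$W, p = obs$p, q = q,
             row.names = NULL, stringsAsFactors = FALSE)
}
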