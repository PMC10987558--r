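#' Bray-Curtis dissimilarity matrix
#'
#' D_jk = sum|x_j - x_k| / sum(x_j + x_k) over genera, computed with
#' [vegan::vegdist()]. Bounded in \[0, 1\] for non-negative data; 0 for
#' identical samples, 1 for samples with disjoint genus support.
#'
#' @param table an [AbundanceTable-class]; relative abundances recommended.
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
brayCurtis <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  a <- abundances(table)
  cs <- colSums(a)
  if (sum(cs <= 0) >= 2)
    stop("Bray-Curtis undefined: more than one all-zero sample")
  d <- as.matrix(vegan::vegdist(t(a), method = "bray"))
  dimnames(d) <- list(colnames(a), colnames(a))
  d
}

# Anderson's pseudo-F from a distance matrix and a grouping: total vs
# within-group sums of squared distances.
pseudoF <- function(D2, labels) {
  n <- nrow(D2)
  groups <- split(seq_len(n), labels)
  sst <- sum(D2[upper.tri(D2)]) / n
  ssw <- sum(vapply(groups, function(idx) {
    sub <- D2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  g <- length(groups)
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: Anderson's pseudo-F from
#' total and within-group sums of squared distances, with significance from
#' free permutation of the sample labels. The p-value is
#' (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param D square symmetric distance matrix (e.g. from [brayCurtis()]).
#' @param labels group label per sample (>= 2 nonempty groups).
#' @param nPerm number of label permutations (default 1000).
#' @param seed integer seed, mandatory: permutations are always reproducible.
#' @param permMatrix optional integer matrix (nPerm x n) of explicit
#'   permutations; overrides random permutation (used e.g. for exhaustive
#'   enumeration on small designs).
#' @return list with `F` (pseudo-F), `p`, `nPerm`, `seed`.
#' @export
permanova <- function(D, labels, nPerm = 1000, seed, permMatrix = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("D must be square")
  n <- nrow(D)
  if (length(labels) != n) stop("labels length must match D")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("PERMANOVA needs at least 2 groups")
  if (is.null(permMatrix)) {
    assertScalarNumber(nPerm, "nPerm", lower = 1, integer = TRUE)
    if (missing(seed)) stop("a seed is required")
  }
  D2 <- D^2
  fObs <- pseudoF(D2, labels)
  if (is.null(permMatrix)) {
    fPerm <- withSeed(seed, {
      vapply(seq_len(nPerm), function(b)
        pseudoF(D2, labels[sample.int(n)]), numeric(1))
    })
  } else {
    nPerm <- nrow(permMatrix)
    fPerm <- vapply(seq_len(nPerm), function(b)
      pseudoF(D2, labels[permMatrix[b, ]]), numeric(1))
    seed <- NA_integer_
  }
  p <- (1 + sum(fPerm >= fObs - 1e-12)) / (1 + nPerm)
  list(F = fObs, p = p, nPerm = nPerm, seed = seed)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix ([stats::cmdscale()]):
#' eigen-decomposition of the double-centered -D^2/2 matrix. Axes with
#' negative eigenvalues are never returned; their magnitudes are reported so
#' the caller can judge how non-Euclidean the distances are.
#'
#' @param D square distance matrix.
#' @param k number of axes requested (must not exceed the number of positive
#'   eigenvalues).
#' @param cailliez apply the Cailliez additive correction before the
#'   decomposition (default `FALSE`).
#' @return list with `coordinates` (n x k matrix), `eigenvalues` (all),
#'   `negativeEigenvalues` (magnitudes), `varianceExplained` over positive
#'   eigenvalues.
#' @export
pcoa <- function(D, k = 2, cailliez = FALSE) {
  D <- as.matrix(D)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = min(nrow(D) - 1, k),
                    eig = TRUE, add = cailliez))
  eig <- fit$eig
  npos <- sum(eig > 1e-8)
  if (k > npos)
    stop(sprintf("k = %d exceeds the %d positive eigenvalues", k, npos))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  rownames(coords) <- rownames(D)
  list(coordinates = coords, eigenvalues = eig,
       negativeEigenvalues = abs(eig[eig < -1e-8]),
       varianceExplained = eig[seq_len(k)] / sum(eig[eig > 0]))
}
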