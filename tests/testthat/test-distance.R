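relTable <- function(X) {  # X: samples x genera
  m <- t(X)
  dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  abundanceTable(sweep(m, 2, colSums(m), "/"), normalized = TRUE)
}

test_that("Bray-Curtis matches the defining formula", {
  ident <- relTable(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(max(abs(brayCurtis(ident))), 0)

  disjoint <- relTable(rbind(c(1, 1, 0, 0), c(0, 0, 2, 5)))
  expect_equal(brayCurtis(disjoint)[1, 2], 1)

  set.seed(11)
  X <- matrix(rexp(40), 5, 8)
  tab <- relTable(X)
  D <- brayCurtis(tab)
  Xrel <- t(abundances(tab))
  expect_equal(unname(D), unname(bruteBrayCurtis(Xrel)), tolerance = 1e-12)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
})

test_that("PERMANOVA pseudo-F and p behave as specified", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  D <- as.matrix(dist(X))
  labels <- rep(c("a", "b"), each = 5)

  expect_error(permanova(D, rep("a", 10), nPerm = 99, seed = 1),
               "2 groups")
  expect_error(permanova(D, labels, nPerm = 99), "seed")

  # maximally separated point clouds: observed F exceeds every permutation
  # (clouds large enough that no random permutation recreates the split)
  D2 <- matrix(1, 20, 20)
  D2[1:10, 1:10] <- 0
  D2[11:20, 11:20] <- 0
  diag(D2) <- 0
  res <- permanova(D2, rep(c("a", "b"), each = 10), nPerm = 199, seed = 9)
  expect_equal(res$p, 1 / 200)

  # independently coded pseudo-F agrees
  own <- fluxbiome:::pseudoF(D^2, labels)
  expect_equal(own, brutePseudoF(D, labels), tolerance = 1e-10)

  # cross-check against vegan's implementation of the same statistic
  ad <- vegan::adonis2(as.dist(D) ~ g,
                       data = data.frame(g = labels), permutations = 2)
  expect_equal(own, ad$F[1], tolerance = 1e-8)
})

test_that("PERMANOVA p matches exhaustive enumeration on 6 samples", {
  set.seed(5)
  X <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(X))
  labels <- rep(c("a", "b"), each = 3)
  allPerms <- t(sapply(combn(6, 3, simplify = FALSE), function(idx) {
    p <- integer(6)
    p[1:3] <- idx          # samples taking label 'a'
    p[4:6] <- setdiff(1:6, idx)
    p
  }))
  res <- permanova(D, labels, permMatrix = allPerms)
  # independent enumeration with the brute-force pseudo-F
  fObs <- brutePseudoF(D, labels)
  fAll <- apply(allPerms, 1, function(p) brutePseudoF(D, labels[p]))
  pOracle <- (1 + sum(fAll >= fObs - 1e-12)) / (1 + length(fAll))
  expect_equal(res$p, pOracle)
})

test_that("PCoA embeds Euclidean configurations faithfully", {
  # points on a line: the first axis reproduces pairwise distances
  x <- c(0, 1, 3, 7)
  D <- as.matrix(dist(x))
  fit <- pcoa(D, k = 1)
  expect_equal(as.matrix(dist(fit$coordinates[, 1])), unname(D),
               tolerance = 1e-8, ignore_attr = TRUE)

  # random 2-D configuration is recovered up to rotation
  set.seed(8)
  P <- matrix(rnorm(20), 10, 2)
  D2 <- as.matrix(dist(P))
  fit2 <- pcoa(D2, k = 2)
  expect_equal(as.matrix(dist(fit2$coordinates)), unname(D2),
               tolerance = 1e-8, ignore_attr = TRUE)

  # duplicated sample lands on identical coordinates
  P3 <- rbind(P, P[1, ])
  fit3 <- pcoa(as.matrix(dist(P3)), k = 2)
  expect_equal(fit3$coordinates[11, ], fit3$coordinates[1, ],
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(pcoa(D2, k = 9), "positive eigenvalues")
})
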