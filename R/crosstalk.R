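# Align two compartment tables by subject: returns subject-by-genus matrices
# restricted to subjects present in both compartments.
pairBySubject <- function(oral, faecal) {
  so <- sampleData(oral)
  sf <- sampleData(faecal)
  if (!"subject_id" %in% names(so) || !"subject_id" %in% names(sf))
    stop("sample metadata must carry 'subject_id' for pairing")
  common <- intersect(so$subject_id, sf$subject_id)
  oi <- match(common, so$subject_id)
  fi <- match(common, sf$subject_id)
  list(subjects = common,
       oral = t(abundances(oral))[oi, , drop = FALSE],
       faecal = t(abundances(faecal))[fi, , drop = FALSE],
       oralGroups = as.character(so$group[oi]))
}

#' Cross-compartment Spearman correlation of genus abundances
#'
#' Spearman rho (and approximate p) for every (oral genus, faecal genus)
#' pair across subjects sampled in both compartments. Display thresholds for
#' significance stars are p < 0.05 (*) and p < 0.01 (**); all raw p-values
#' are returned.
#'
#' @param oral,faecal [AbundanceTable-class] objects for the two
#'   compartments, paired through the `subject_id` metadata column.
#' @param group restrict to subjects of one group (optional).
#' @return list with `rho` and `p` matrices (oral genera x faecal genera),
#'   `stars` character matrix, and `n` (number of paired subjects).
#' @export
crossCompartmentCorrelation <- function(oral, faecal, group = NULL) {
  pr <- pairBySubject(oral, faecal)
  keep <- if (is.null(group)) seq_along(pr$subjects)
          else which(pr$oralGroups == group)
  if (length(keep) < 3) stop("need at least 3 paired subjects")
  O <- pr$oral[keep, , drop = FALSE]
  F_ <- pr$faecal[keep, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(O, F_, method = "spearman"))
  n <- length(keep)
  # t approximation on ranks (AS89-style); exact p is not defined with ties
  tstat <- rho * sqrt((n - 2) / pmax(1e-12, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.finite(p)] <- 0  # |rho| == 1
  p[is.na(rho)] <- 1
  rho[is.na(rho)] <- 0
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  list(rho = rho, p = p, stars = stars, n = n)
}

#' Shared-genus compartmentalization analysis
#'
#' Quantifies how separate the oral and faecal communities are. Pooled per
#' group: Venn counts of genera detected (above `threshold` in at least one
#' sample of the compartment-group). Per individual: the percentage of
#' shared genera, 100 * |oral_i intersect faecal_i| / |oral_i union
#' faecal_i|, compared between groups with a Wilcoxon rank-sum test.
#'
#' @param oral,faecal paired [AbundanceTable-class] objects.
#' @param threshold detection threshold on the stored values (default 0:
#'   any nonzero abundance counts as present).
#' @return list with per-group elements `venn` (oralOnly, shared,
#'   faecalOnly), `sharedPercent` (per individual), and `wilcoxonP` across
#'   the first two groups.
#' @export
sharedGenusAnalysis <- function(oral, faecal, threshold = 0) {
  pr <- pairBySubject(oral, faecal)
  groups <- sort(unique(pr$oralGroups))
  out <- list()
  for (g in groups) {
    idx <- which(pr$oralGroups == g)
    O <- pr$oral[idx, , drop = FALSE]
    F_ <- pr$faecal[idx, , drop = FALSE]
    if (any(rowSums(O) == 0) || any(rowSums(F_) == 0))
      stop(sprintf("empty compartment for a subject in group '%s'", g))
    oralSet <- colnames(O)[apply(O > threshold, 2, any)]
    faecalSet <- colnames(F_)[apply(F_ > threshold, 2, any)]
    shared <- intersect(oralSet, faecalSet)
    perc <- vapply(seq_along(idx), function(i) {
      oi <- colnames(O)[O[i, ] > threshold]
      fi <- colnames(F_)[F_[i, ] > threshold]
      u <- union(oi, fi)
      if (length(u) == 0) return(0)
      100 * length(intersect(oi, fi)) / length(u)
    }, numeric(1))
    out[[g]] <- list(
      venn = c(oralOnly = length(setdiff(oralSet, shared)),
               shared = length(shared),
               faecalOnly = length(setdiff(faecalSet, shared))),
      sharedPercent = stats::setNames(perc, pr$subjects[idx]))
  }
  if (length(groups) >= 2) {
    w <- suppressWarnings(stats::wilcox.test(
      out[[groups[1]]]$sharedPercent, out[[groups[2]]]$sharedPercent))
    out$wilcoxonP <- w$p.value
    out$comparedGroups <- groups[1:2]
  }
  out
}
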