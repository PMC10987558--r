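#' Alpha diversity: Shannon index and specific richness
#'
#' Computes, per sample, the Shannon index in natural-log units (nats),
#' H = -sum(p * log(p)) with the 0 * log(0) = 0 convention, and the specific
#' richness (number of genera with nonzero abundance). Divide H by `log(2)`
#' for bits. Computed through [vegan::diversity()].
#'
#' @param table a normalized [AbundanceTable-class] (see [toRelative()]).
#' @return `data.frame` with columns `sample_id`, `shannon`, `richness`.
#' @examples
#' m <- matrix(rep(0.25, 4), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), "s1"))
#' shannonDiversity(abundanceTable(m, normalized = TRUE))  # ln(4), 4
#' @export
shannonDiversity <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  if (!isNormalized(table))
    stop("shannonDiversity expects a normalized table; see toRelative()")
  a <- abundances(table)
  if (any(a < 0)) stop("negative abundances")
  h <- vegan::diversity(t(a), index = "shannon")
  rich <- colSums(a > 0)
  data.frame(sample_id = colnames(a), shannon = unname(h),
             richness = unname(rich), stringsAsFactors = FALSE)
}

#' Spearman association between Shannon diversity and age, per group
#'
#' Used to ask whether diversity drifts with age differently in patients and
#' controls. A group whose Shannon values (or ages) are constant has an
#' undefined rank correlation; it is reported as rho = 0, p = 1 with
#' `tied = TRUE`.
#'
#' @param diversity output of [shannonDiversity()].
#' @param metadata data.frame with `sample_id`, `group` and `age` columns.
#' @param groups groups to test; default all groups present.
#' @return `data.frame` with one row per group: `group`, `n`, `rho`, `p`,
#'   `tied`.
#' @export
ageDiversityAssociation <- function(diversity, metadata, groups = NULL) {
  stopifnot(all(c("sample_id", "group", "age") %in% names(metadata)))
  m <- merge(diversity, metadata[, c("sample_id", "group", "age")],
             by = "sample_id")
  if (anyNA(m$age)) stop("missing ages for samples: ",
                         paste(m$sample_id[is.na(m$age)], collapse = ", "))
  if (is.null(groups)) groups <- sort(unique(m$group))
  res <- lapply(groups, function(g) {
    d <- m[m$group == g, ]
    if (nrow(d) < 4)
      stop(sprintf("group '%s' has fewer than 4 aged samples", g))
    if (length(unique(d$shannon)) == 1L || length(unique(d$age)) == 1L)
      return(data.frame(group = g, n = nrow(d), rho = 0, p = 1, tied = TRUE))
    ct <- suppressWarnings(
      stats::cor.test(d$shannon, d$age, method = "spearman", exact = FALSE))
    data.frame(group = g, n = nrow(d), rho = unname(ct$estimate),
               p = ct$p.value, tied = FALSE)
  })
  do.call(rbind, res)
}

#' qPCR relative quantification (delta-delta Ct)
#'
#' Relative expression of a target gene against a reference gene and a
#' baseline group: dCt = Ct_target - Ct_reference, ddCt = dCt -
#' mean(dCt over the baseline group), relative level = 2^(-ddCt).
#'
#' @param ctTarget,ctReference numeric Ct vectors, paired per sample.
#' @param groupLabels group per sample.
#' @param baselineGroup label of the calibrator group.
#' @return `data.frame` with `group`, `dct`, `ddct`, `level`.
#' @export
deltaDeltaCt <- function(ctTarget, ctReference, groupLabels, baselineGroup) {
  if (length(ctTarget) != length(ctReference) ||
      length(ctTarget) != length(groupLabels))
    stop("ctTarget, ctReference and groupLabels must have equal length")
  if (anyNA(ctTarget) || anyNA(ctReference)) stop("missing Ct values")
  if (!baselineGroup %in% groupLabels) stop("baseline group is empty")
  dct <- ctTarget - ctReference
  ddct <- dct - mean(dct[groupLabels == baselineGroup])
  data.frame(group = groupLabels, dct = dct, ddct = ddct,
             level = 2^(-ddct), stringsAsFactors = FALSE)
}
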