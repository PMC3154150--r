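# Margin-cell index (0-based) of each full cell for a SNP subset: the cell's
# base-3 digits at the subset positions, read as a base-3 number.
marginGroups <- function(k, subset) {
  g <- integer(3L^k)
  for (s in subset) g <- g * 3L + cellDigits(k, s)
  g
}

# All subsets of a given order, as a list of increasing index vectors.
snpSubsets <- function(k, order) {
  stopifnot(order >= 1L, order <= k)
  m <- combn(seq_len(k), order)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

checkSubset <- function(subset, k) {
  subset <- as.integer(subset)
  if (length(subset) < 1L || anyNA(subset) ||
      any(subset < 1L) || any(subset > k) || anyDuplicated(subset) ||
      is.unsorted(subset, strictly = TRUE))
    stop("subset must be a strictly increasing vector of SNP indices in 1..",
         k)
  subset
}

#' MDR accuracy of a SNP subset
#'
#' Multifactor Dimensionality Reduction collapses the dataset onto the
#' `3^|subset|` multi-locus genotype cells of the chosen SNPs, labels each
#' cell high-risk when it holds more cases than controls and low-risk
#' otherwise, and scores the labeling by the fraction of subjects it
#' classifies correctly: `sum over cells of max(cases, controls) / n`. For a
#' balanced design the value lies in \[0.5, 1\]; cells with tied (or zero)
#' counts contribute the same amount under either label, so the tie
#' convention (low-risk here, matching displays that darken only
#' case-majority cells) cannot change the accuracy.
#'
#' @param x a [GenotypeCounts-class] or [GenotypeDataset-class]; the design
#'   must be balanced.
#' @param subset strictly increasing vector of SNP indices (1-based).
#' @return accuracy in \[0.5, 1\].
#' @examples
#' tab <- GenotypeCounts(c(3, 1, 1), c(1, 3, 1), 1)
#' mdrAccuracy(tab, 1)  # (3 + 3 + 1) / 10
#' @rdname mdrAccuracy
#' @export
setMethod("mdrAccuracy", "GenotypeCounts", function(x, subset) {
  subset <- checkSubset(subset, x@nSnps)
  if (sum(x@caseCounts) != sum(x@controlCounts))
    stop("MDR accuracy is defined here for balanced designs only ",
         "(equal numbers of cases and controls)")
  g <- marginGroups(x@nSnps, subset)
  ca <- rowsum(x@caseCounts, g)
  co <- rowsum(x@controlCounts, g)
  sum(pmax(ca, co)) / nSubjects(x)
})

#' @rdname mdrAccuracy
#' @export
setMethod("mdrAccuracy", "GenotypeDataset",
          function(x, subset) mdrAccuracy(asCounts(x), subset))

#' Maximum MDR accuracy at an interaction order
#'
#' The largest [mdrAccuracy()] over all `choose(k, order)` SNP subsets of
#' the given order; this is the dataset attribute used for selection. For
#' `order = k` it is the single full-order accuracy. Enumeration is
#' exhaustive (at most 31 subsets for k = 5).
#'
#' @param x a [GenotypeCounts-class] or [GenotypeDataset-class].
#' @param order interaction order, between 1 and `k`.
#' @return accuracy in \[0.5, 1\].
#' @rdname maxOrderAccuracy
#' @export
setMethod("maxOrderAccuracy", "GenotypeCounts", function(x, order) {
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 1L || order > x@nSnps)
    stop("order must lie between 1 and the number of SNPs (", x@nSnps, ")")
  max(vapply(snpSubsets(x@nSnps, order),
             function(s) mdrAccuracy(x, s), numeric(1)))
})

#' @rdname maxOrderAccuracy
#' @export
setMethod("maxOrderAccuracy", "GenotypeDataset",
          function(x, order) maxOrderAccuracy(asCounts(x), order))

# internal: precomputed subset-marginalization context for population-level
# accuracy evaluation (built once per run, reused every generation)
accuracyContext <- function(k, orders) {
  subsets <- unlist(lapply(orders, function(o) snpSubsets(k, o)),
                    recursive = FALSE)
  ord <- rep.int(orders, vapply(orders, function(o) choose(k, o), numeric(1)))
  groups <- vapply(subsets, function(s) marginGroups(k, s), integer(3L^k))
  list(orders = orders,
       groups = matrix(groups, nrow = 3L^k),
       marginSizes = as.integer(3L^lengths(subsets)),
       rowsByOrder = lapply(orders, function(o) which(ord == o)))
}

# internal: per-order max accuracies (orders x datasets) for a population of
# count columns
populationOrderAccuracies <- function(casePop, controlPop, ctx) {
  acc <- cpp_subset_accuracies(casePop, controlPop, ctx$groups,
                               ctx$marginSizes)
  out <- matrix(NA_real_, length(ctx$orders), ncol(casePop))
  for (i in seq_along(ctx$orders)) {
    rows <- ctx$rowsByOrder[[i]]
    out[i, ] <- if (length(rows) == 1L) acc[rows, ]
    else do.call(pmax, lapply(rows, function(r) acc[r, ]))
  }
  rownames(out) <- paste0("acc", ctx$orders)
  out
}
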