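#' Create an ObjectiveSpec
#'
#' The classic three-objective setting minimizes the maximum one-way and
#' two-way MDR accuracies while maximizing the full-order accuracy:
#' `objectiveSpec(c(1, 2), k)`. Minimizing all lower orders for a four- or
#' five-locus dataset is `objectiveSpec(1:(k - 1), k)`. Setting `hwe = TRUE`
#' adds a minimized Hardy-Weinberg chi-square objective so evolved SNPs
#' would pass HWE quality-control filters.
#'
#' @param minimizedOrders interaction orders to minimize (strictly below
#'   `maximizedOrder`).
#' @param maximizedOrder the full order `k`.
#' @param hwe include the HWE chi-square objective.
#' @param hweAggregate `"max"` (default) or `"sum"` over per-SNP statistics.
#' @param hwePooled pool cases and controls for the HWE statistic (default)
#'   or use controls only.
#' @return an [ObjectiveSpec-class].
#' @examples
#' objectiveSpec(c(1, 2), 3)
#' objectiveSpec(1:4, 5)
#' @export
objectiveSpec <- function(minimizedOrders, maximizedOrder, hwe = FALSE,
                          hweAggregate = c("max", "sum"), hwePooled = TRUE) {
  new("ObjectiveSpec",
      minimizedOrders = as.integer(sort(unique(minimizedOrders))),
      maximizedOrder = as.integer(maximizedOrder),
      hwe = isTRUE(hwe), hweAggregate = match.arg(hweAggregate),
      hwePooled = isTRUE(hwePooled))
}

#' Objective metadata
#'
#' `nObjectives()` is the objective-vector length, `objectiveNames()` the
#' component names (`acc<order>` plus `hwe`), and `orientations()` the
#' per-component `"min"`/`"max"` flags.
#'
#' @param spec an [ObjectiveSpec-class].
#' @return integer / character vectors.
#' @export
nObjectives <- function(spec) {
  length(spec@minimizedOrders) + 1L + as.integer(spec@hwe)
}

#' @rdname nObjectives
#' @export
objectiveNames <- function(spec) {
  c(paste0("acc", c(spec@minimizedOrders, spec@maximizedOrder)),
    if (spec@hwe) "hwe")
}

#' @rdname nObjectives
#' @export
orientations <- function(spec) {
  c(rep("min", length(spec@minimizedOrders)), "max",
    if (spec@hwe) "min")
}

setMethod("show", "ObjectiveSpec", function(object) {
  o <- orientations(object)
  cat("ObjectiveSpec:",
      paste0(ifelse(o == "min", "↓", "↑"), objectiveNames(object),
             collapse = " "), "\n")
})

#' Hardy-Weinberg chi-square statistic for one SNP
#'
#' With genotype counts `(n0, n1, n2)` (pooled over cases and controls by
#' default) and allele frequency `p = (2 n0 + n1) / (2 n)`, the expected
#' counts under Hardy-Weinberg equilibrium are
#' `(n p^2, 2 n p (1 - p), n (1 - p)^2)` and the statistic is the usual
#' `sum((obs - exp)^2 / exp)`. It is zero when the observed counts match the
#' expectation exactly, and symmetric under swapping the homozygote labels.
#' A monomorphic SNP (`p` of 0 or 1) has no measurable HWE deviation and
#' returns 0.
#'
#' @param x a [GenotypeCounts-class] or [GenotypeDataset-class].
#' @param snp SNP index (1-based).
#' @param pooled pool cases and controls (default) or use controls only.
#' @return chi-square statistic, `>= 0`.
#' @examples
#' d <- GenotypeCounts(c(15, 20, 15), c(15, 20, 15), 1)
#' hweChiSquare(d, 1)  # counts (30, 40, 30): expected (25, 50, 25) -> 4
#' @rdname hweChiSquare
#' @export
setMethod("hweChiSquare", "GenotypeCounts", function(x, snp, pooled = TRUE) {
  snp <- as.integer(snp)
  if (length(snp) != 1L || is.na(snp) || snp < 1L || snp > x@nSnps)
    stop("snp must be a single index in 1..", x@nSnps)
  counts <- if (pooled) x@caseCounts + x@controlCounts else x@controlCounts
  obs <- as.vector(rowsum(counts, cellDigits(x@nSnps, snp)))
  hweChiSquareFromCounts(obs)
})

#' @rdname hweChiSquare
#' @export
setMethod("hweChiSquare", "GenotypeDataset",
          function(x, snp, pooled = TRUE) hweChiSquare(asCounts(x), snp,
                                                       pooled))

hweChiSquareFromCounts <- function(obs) {
  n <- sum(obs)
  p <- (2 * obs[1] + obs[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(0)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  sum((obs - expd)^2 / expd)
}

#' Evaluate a dataset's objective vector
#'
#' Computes the attributes driving selection: the maximum MDR accuracy at
#' each minimized order, the full-order MDR accuracy, and (if active) the
#' Hardy-Weinberg chi-square objective aggregated over SNPs (maximum by
#' default, so the worst SNP is what the objective guards).
#'
#' @param x a [GenotypeCounts-class] or [GenotypeDataset-class] (balanced).
#' @param spec an [ObjectiveSpec-class].
#' @return named numeric vector with one entry per objective, in the order
#'   given by [objectiveNames()].
#' @examples
#' spec <- objectiveSpec(c(1, 2), 3)
#' evaluateObjectives(initCounts(3000, 3), spec)
#' @rdname evaluateObjectives
#' @export
setMethod("evaluateObjectives", "GenotypeCounts", function(x, spec) {
  if (spec@maximizedOrder != x@nSnps)
    stop("spec maximizedOrder (", spec@maximizedOrder,
         ") must equal the dataset's SNP count (", x@nSnps, ")")
  acc <- vapply(c(spec@minimizedOrders, spec@maximizedOrder),
                function(o) maxOrderAccuracy(x, o), numeric(1))
  v <- c(acc, if (spec@hwe) hweObjective(x@caseCounts, x@controlCounts,
                                         x@nSnps, spec))
  setNames(v, objectiveNames(spec))
})

#' @rdname evaluateObjectives
#' @export
setMethod("evaluateObjectives", "GenotypeDataset",
          function(x, spec) evaluateObjectives(asCounts(x), spec))

# internal: HWE objective for one table held as count vectors
hweObjective <- function(caseCounts, controlCounts, k, spec) {
  counts <- if (spec@hwePooled) caseCounts + controlCounts else controlCounts
  stat <- vapply(seq_len(k), function(s) {
    hweChiSquareFromCounts(as.vector(rowsum(counts, cellDigits(k, s))))
  }, numeric(1))
  if (spec@hweAggregate == "max") max(stat) else sum(stat)
}

# internal: reusable evaluation context for a (k, spec) pair
objectiveContext <- function(k, spec) {
  ctx <- accuracyContext(k, c(spec@minimizedOrders, spec@maximizedOrder))
  ctx$digits <- lapply(seq_len(k), function(s) cellDigits(k, s))
  ctx
}

# internal: population-level objective matrix (objectives x datasets)
populationObjectives <- function(casePop, controlPop, k, spec,
                                 ctx = objectiveContext(k, spec)) {
  acc <- populationOrderAccuracies(casePop, controlPop, ctx)
  if (spec@hwe) {
    counts <- if (spec@hwePooled) casePop + controlPop else controlPop
    stats <- vapply(seq_len(k), function(s) {
      m <- rowsum(counts, ctx$digits[[s]])   # 3 x P genotype margins
      n <- colSums(m)
      p <- (2 * m[1, ] + m[2, ]) / (2 * n)
      q <- 1 - p
      e0 <- n * p^2; e1 <- 2 * n * p * q; e2 <- n * q^2
      chi <- (m[1, ] - e0)^2 / e0 + (m[2, ] - e1)^2 / e1 +
        (m[3, ] - e2)^2 / e2
      ifelse(p <= 0 | p >= 1, 0, chi)
    }, numeric(ncol(casePop)))
    stats <- matrix(stats, nrow = ncol(casePop))
    hwe <- if (spec@hweAggregate == "max") {
      do.call(pmax, as.data.frame(stats))
    } else {
      rowSums(stats)
    }
    acc <- rbind(acc, hwe = hwe)
  }
  rownames(acc) <- objectiveNames(spec)
  acc
}
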