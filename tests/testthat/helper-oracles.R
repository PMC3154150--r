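# Independent brute-force oracles used to validate the fast paths.

# random small balanced contingency table
randomTable <- function(k, nPerClass = 20) {
  GenotypeCounts(rmultinom(1, nPerClass, rep(1 / 3^k, 3^k)),
                 rmultinom(1, nPerClass, rep(1 / 3^k, 3^k)), k)
}

# classify-then-count oracle: label every margin cell by case/control
# majority on the expanded subject matrix, then count correct subjects
oracleMdrAccuracy <- function(tab, subset) {
  d <- asDataset(tab)
  g <- genotypes(d)[, subset, drop = FALSE]
  key <- apply(g, 1, paste, collapse = ":")
  cls <- status(d)
  correct <- 0L
  for (cell in unique(key)) {
    inCell <- key == cell
    nCase <- sum(cls[inCell] == 1L)
    nCtrl <- sum(inCell) - nCase
    label <- if (nCase > nCtrl) 1L else 0L
    correct <- correct + sum(cls[inCell] == label)
  }
  correct / length(cls)
}

# O(n^2) non-dominated filter straight from the definition
oracleParetoFilter <- function(objectives, orientations) {
  n <- nrow(objectives)
  keep <- logical(n)
  for (i in seq_len(n)) {
    keep[i] <- !any(vapply(seq_len(n)[-i], function(j)
      dominates(objectives[j, ], objectives[i, ], orientations),
      logical(1)))
  }
  which(keep)
}

# objective vector computed entirely from the subject-level matrix path
oracleObjectives <- function(dataset, spec) {
  g <- genotypes(dataset)
  cls <- status(dataset)
  k <- ncol(g)
  accOf <- function(subset) {
    tab <- asCounts(GenotypeDataset(g, cls))
    oracleMdrAccuracy(tab, subset)
  }
  orders <- c(spec@minimizedOrders, spec@maximizedOrder)
  acc <- vapply(orders, function(o)
    max(vapply(epiForge:::snpSubsets(k, o), accOf, numeric(1))), numeric(1))
  v <- acc
  if (spec@hwe) {
    chi <- vapply(seq_len(k), function(s) {
      obs <- tabulate(g[, s] + 1L, 3L)
      n <- sum(obs)
      p <- (2 * obs[1] + obs[2]) / (2 * n)
      if (p <= 0 || p >= 1) return(0)
      e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
      sum((obs - e)^2 / e)
    }, numeric(1))
    v <- c(v, if (spec@hweAggregate == "max") max(chi) else sum(chi))
  }
  setNames(v, objectiveNames(spec))
}

# tiny table constructors used across files
table1snp <- function(caseCounts, controlCounts)
  GenotypeCounts(caseCounts, controlCounts, 1)
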