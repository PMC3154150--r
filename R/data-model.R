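# Genotype state frequencies at initialization: minor and major allele
# frequency 0.5 under Hardy-Weinberg proportions.
.INIT_GENO_PROBS <- c(0.25, 0.50, 0.25)

# Cell probabilities over the 3^k genotype cells implied by independent SNPs
# at the initialization frequencies (SNP 1 = most significant base-3 digit).
cellProbabilities <- function(k) {
  p <- .INIT_GENO_PROBS
  out <- 1
  for (i in seq_len(k)) out <- as.vector(outer(p, out))
  out
}

# base-3 digit of each cell index (1-based cells) for a given SNP
cellDigits <- function(k, snp) {
  (as.integer((seq_len(3L^k) - 1L) %/% 3L^(k - snp))) %% 3L
}

#' Create a GenotypeDataset
#'
#' @param genotypes matrix of 0/1/2 genotypes, one row per subject.
#' @param status vector of 0/1 class labels (1 = case).
#' @return a validated [GenotypeDataset-class].
#' @export
GenotypeDataset <- function(genotypes, status) {
  g <- as.matrix(genotypes)
  storage.mode(g) <- "integer"
  new("GenotypeDataset", genotypes = g, status = as.integer(status))
}

#' Create a GenotypeCounts object
#'
#' @param caseCounts,controlCounts integer vectors of length `3^nSnps`.
#' @param nSnps number of SNPs `k`.
#' @return a validated [GenotypeCounts-class].
#' @export
GenotypeCounts <- function(caseCounts, controlCounts, nSnps) {
  new("GenotypeCounts", caseCounts = as.integer(caseCounts),
      controlCounts = as.integer(controlCounts), nSnps = as.integer(nSnps))
}

#' @describeIn nSubjects number of subjects in a dataset
#' @export
setMethod("nSubjects", "GenotypeDataset", function(x) length(x@status))

#' Number of subjects
#'
#' @param x a dataset, counts object, or config.
#' @return integer.
#' @rdname nSubjects
#' @export
setMethod("nSubjects", "GenotypeCounts",
          function(x) sum(x@caseCounts) + sum(x@controlCounts))

#' Number of SNPs
#'
#' @param x a dataset, counts object, or config.
#' @return integer.
#' @rdname nSnps
#' @export
setMethod("nSnps", "GenotypeDataset", function(x) ncol(x@genotypes))

#' @rdname nSnps
#' @export
setMethod("nSnps", "GenotypeCounts", function(x) x@nSnps)

#' Per-class genotype-cell counts
#'
#' @param x a [GenotypeCounts-class].
#' @return integer vector of length `3^k`.
#' @rdname caseCounts
#' @export
setMethod("caseCounts", "GenotypeCounts", function(x) x@caseCounts)

#' @rdname caseCounts
#' @export
setMethod("controlCounts", "GenotypeCounts", function(x) x@controlCounts)

#' Genotype matrix and status vector of a dataset
#'
#' @param x a [GenotypeDataset-class].
#' @return `genotypes()`: integer matrix; `status()`: integer vector.
#' @rdname genotypes
#' @export
setMethod("genotypes", "GenotypeDataset", function(x) x@genotypes)

#' @rdname genotypes
#' @export
setMethod("status", "GenotypeDataset", function(x) x@status)

setMethod("show", "GenotypeDataset", function(object) {
  cat(sprintf("GenotypeDataset: %d subjects (%d cases / %d controls), %d SNPs\n",
              nSubjects(object), sum(object@status == 1L),
              sum(object@status == 0L), nSnps(object)))
})

setMethod("show", "GenotypeCounts", function(object) {
  cat(sprintf(
    "GenotypeCounts: %d SNPs, %d cells, %d cases / %d controls\n",
    object@nSnps, 3L^object@nSnps, sum(object@caseCounts),
    sum(object@controlCounts)))
})

#' Initialize a random balanced dataset
#'
#' Subjects are split equally into cases and controls; every genotype is
#' drawn independently with probabilities (0.25, 0.5, 0.25) for states
#' (0, 1, 2) — Hardy-Weinberg proportions at minor allele frequency 0.5.
#' `initDataset()` returns the subject-level matrix form (cases first);
#' `initCounts()` draws the equivalent per-class multinomial cell counts
#' directly, which is the fast path used by [evolve()] and [randomSearch()].
#'
#' @param nSubjects even positive number of subjects.
#' @param nSnps number of SNPs.
#' @return [GenotypeDataset-class] or [GenotypeCounts-class].
#' @examples
#' initDataset(10, 3)
#' initCounts(3000, 3)
#' @export
initDataset <- function(nSubjects, nSnps) {
  if (nSubjects %% 2 != 0 || nSubjects < 2)
    stop("nSubjects must be even and positive: each dataset holds exactly ",
         "n/2 cases and n/2 controls")
  g <- matrix(sample(0:2, nSubjects * nSnps, replace = TRUE,
                     prob = .INIT_GENO_PROBS),
              nrow = nSubjects, ncol = nSnps)
  GenotypeDataset(g, rep(c(1L, 0L), each = nSubjects / 2))
}

#' @rdname initDataset
#' @export
initCounts <- function(nSubjects, nSnps) {
  if (nSubjects %% 2 != 0 || nSubjects < 2)
    stop("nSubjects must be even and positive: each dataset holds exactly ",
         "n/2 cases and n/2 controls")
  p <- cellProbabilities(nSnps)
  GenotypeCounts(rmultinom(1, nSubjects / 2, p),
                 rmultinom(1, nSubjects / 2, p), nSnps)
}

# internal: population of count columns (3^k x popSize per class)
initCountPopulation <- function(nSubjects, nSnps, popSize) {
  p <- cellProbabilities(nSnps)
  list(case = rmultinom(popSize, nSubjects / 2, p),
       control = rmultinom(popSize, nSubjects / 2, p))
}

#' @describeIn asCounts collapse a dataset to contingency counts
#' @export
setMethod("asCounts", "GenotypeDataset", function(x) {
  k <- nSnps(x)
  cell <- as.vector(x@genotypes %*% 3L^((k - 1):0)) + 1L
  GenotypeCounts(tabulate(cell[x@status == 1L], nbins = 3L^k),
                 tabulate(cell[x@status == 0L], nbins = 3L^k), k)
})

#' @describeIn asCounts identity on counts
#' @export
setMethod("asCounts", "GenotypeCounts", function(x) x)

#' @describeIn asCounts expand counts to the canonical subject matrix
#' @export
setMethod("asDataset", "GenotypeCounts", function(x) {
  k <- x@nSnps
  cells <- seq_len(3L^k)
  expand <- function(counts) rep.int(cells, counts)
  cell <- c(expand(x@caseCounts), expand(x@controlCounts)) - 1L
  g <- vapply(seq_len(k), function(s) as.integer(cell %/% 3L^(k - s)) %% 3L,
              integer(length(cell)))
  g <- matrix(as.integer(g), ncol = k)
  GenotypeDataset(g, rep(c(1L, 0L), c(sum(x@caseCounts),
                                      sum(x@controlCounts))))
})

#' @describeIn asCounts identity on datasets
#' @export
setMethod("asDataset", "GenotypeDataset", function(x) x)

#' Mutate a dataset
#'
#' Each of the `n x k` genotype entries mutates independently with
#' probability `rate`; a mutated entry is replaced by one of the two other
#' genotype states with equal probability (so a mutation always changes the
#' value; set `resampleSame = TRUE` to draw uniformly over all three states
#' instead, which lowers the effective rate to 2/3 of the nominal one).
#' Status labels are never touched, so class balance is conserved.
#'
#' The [GenotypeCounts-class] method applies the exact count-level
#' equivalent: per SNP, the number of mutating subjects in each genotype
#' cell follows independent `Binomial(count, rate)` thinning, and each
#' mutating subject moves to the cell implied by its new genotype. Subjects
#' within a cell are exchangeable, so both representations induce the same
#' distribution over contingency tables.
#'
#' @param x a [GenotypeDataset-class] or [GenotypeCounts-class].
#' @param rate per-entry mutation probability in \[0, 1\].
#' @param resampleSame logical, see above.
#' @param ... passed to methods.
#' @return an object of the same class as `x`.
#' @examples
#' d <- initDataset(100, 3)
#' m <- mutate(d, 0.01)
#' sum(genotypes(m) != genotypes(d))
#' @rdname mutate
#' @export
setMethod("mutate", "GenotypeDataset", function(x, rate, resampleSame = FALSE) {
  checkRate(rate)
  g <- x@genotypes
  hit <- which(runif(length(g)) < rate)
  if (length(hit)) {
    if (resampleSame) {
      g[hit] <- sample(0:2, length(hit), replace = TRUE)
    } else {
      shift <- sample(1:2, length(hit), replace = TRUE)
      g[hit] <- (g[hit] + shift) %% 3L
    }
  }
  new("GenotypeDataset", genotypes = g, status = x@status)
})

#' @rdname mutate
#' @export
setMethod("mutate", "GenotypeCounts", function(x, rate, resampleSame = FALSE) {
  checkRate(rate)
  m <- cpp_mutate_counts(matrix(x@caseCounts), matrix(x@controlCounts),
                         x@nSnps, rate, resampleSame)
  GenotypeCounts(m$case[, 1L], m$control[, 1L], x@nSnps)
})

checkRate <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("mutation rate must be a single probability in [0, 1]")
  invisible(rate)
}
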