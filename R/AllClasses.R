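#' GenotypeDataset: a balanced case-control genotype matrix
#'
#' The subject-level representation of a dataset: an `n x k` integer matrix of
#' genotypes coded 0/1/2 (1 = heterozygous) and a binary status vector
#' (1 = case, 0 = control). The design is always balanced: exactly `n/2`
#' cases and `n/2` controls.
#'
#' @slot genotypes integer matrix, `n` subjects by `k` SNPs, entries in
#'   \{0, 1, 2\}.
#' @slot status integer vector of length `n`, entries in \{0, 1\}; never
#'   altered by mutation.
#'
#' @seealso [initDataset()], [asCounts()], [mutate()]
#' @exportClass GenotypeDataset
setClass("GenotypeDataset",
  representation(genotypes = "matrix", status = "integer"))

setValidity("GenotypeDataset", function(object) {
  g <- object@genotypes
  s <- object@status
  msg <- character()
  if (!is.numeric(g)) msg <- c(msg, "genotypes must be a numeric matrix")
  else {
    if (nrow(g) != length(s))
      msg <- c(msg, "status length must equal number of genotype rows")
    if (length(g) && !all(g %in% c(0L, 1L, 2L)))
      msg <- c(msg, "genotype entries must be 0, 1 or 2")
    if (ncol(g) < 1L) msg <- c(msg, "at least one SNP is required")
  }
  if (!all(s %in% c(0L, 1L)))
    msg <- c(msg, "status entries must be 0 (control) or 1 (case)")
  if (length(s) %% 2L != 0L || sum(s == 1L) != length(s) / 2L)
    msg <- c(msg, "design must be balanced: n/2 cases and n/2 controls")
  if (length(msg)) msg else TRUE
})

#' GenotypeCounts: contingency-table representation of a dataset
#'
#' The canonical internal form of a dataset: per-class subject counts over
#' all `3^k` genotype cells. Cell index of a genotype vector `(g_1..g_k)` is
#' `sum_j g_j * 3^(k-1-j) + 1` (SNP 1 is the most significant base-3 digit).
#' Subjects within a cell are exchangeable, so this is a lossless sufficient
#' statistic for every MDR accuracy, for the Hardy-Weinberg chi-square and
#' for mutation; it makes full-scale evolution runs cheap.
#'
#' @slot caseCounts integer vector of length `3^k`; case subjects per cell.
#' @slot controlCounts integer vector of length `3^k`.
#' @slot nSnps integer, the number of SNPs `k`.
#'
#' @seealso [initCounts()], [asDataset()], [mdrAccuracy()]
#' @exportClass GenotypeCounts
setClass("GenotypeCounts",
  representation(caseCounts = "integer", controlCounts = "integer",
                 nSnps = "integer"))

setValidity("GenotypeCounts", function(object) {
  k <- object@nSnps
  msg <- character()
  if (length(k) != 1L || is.na(k) || k < 1L)
    msg <- c(msg, "nSnps must be a single positive integer")
  else if (length(object@caseCounts) != 3L^k ||
           length(object@controlCounts) != 3L^k)
    msg <- c(msg, sprintf("count vectors must have length 3^k = %d", 3L^k))
  if (any(object@caseCounts < 0L) || any(object@controlCounts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (sum(object@caseCounts) != sum(object@controlCounts))
    msg <- c(msg, "design must be balanced: equal case and control totals")
  if (length(msg)) msg else TRUE
})

#' ObjectiveSpec: which attributes drive selection
#'
#' Defines a dataset's objective vector: the maximum MDR accuracy at each
#' minimized interaction order, the full-order MDR accuracy (maximized), and
#' optionally a Hardy-Weinberg chi-square deviation objective (minimized).
#'
#' @slot minimizedOrders integer vector of interaction orders whose maximum
#'   MDR accuracy is minimized, all strictly below `maximizedOrder`.
#' @slot maximizedOrder integer, the full interaction order `k`.
#' @slot hwe logical; include the HWE chi-square objective.
#' @slot hweAggregate `"max"` (default) or `"sum"`: how per-SNP chi-squares
#'   combine into one attribute.
#' @slot hwePooled logical; compute HWE on pooled cases + controls (default)
#'   or on controls only.
#'
#' @seealso [objectiveSpec()], [evaluateObjectives()]
#' @exportClass ObjectiveSpec
setClass("ObjectiveSpec",
  representation(minimizedOrders = "integer", maximizedOrder = "integer",
                 hwe = "logical", hweAggregate = "character",
                 hwePooled = "logical"))

setValidity("ObjectiveSpec", function(object) {
  msg <- character()
  mo <- object@minimizedOrders
  k <- object@maximizedOrder
  if (length(k) != 1L || is.na(k) || k < 1L)
    msg <- c(msg, "maximizedOrder must be a single positive integer")
  if (length(mo)) {
    if (any(mo < 1L) || any(mo >= k))
      msg <- c(msg, "minimizedOrders must lie strictly below maximizedOrder")
    if (is.unsorted(mo, strictly = TRUE))
      msg <- c(msg, "minimizedOrders must be strictly increasing")
  }
  if (!object@hweAggregate %in% c("max", "sum"))
    msg <- c(msg, "hweAggregate must be 'max' or 'sum'")
  if (length(msg)) msg else TRUE
})

#' ParetoFront: the non-dominated datasets of a population
#'
#' Holds the mutually non-dominated datasets of a selection step together
#' with their objective vectors. Members with identical objective vectors are
#' all retained; they are distinct datasets.
#'
#' @slot members list of [GenotypeCounts-class] objects.
#' @slot objectives numeric matrix, one row per member, one column per
#'   objective (named as in [objectiveNames()]).
#' @slot spec the [ObjectiveSpec-class] the objectives were computed under.
#'
#' @seealso [paretoFilter()], [capFront()], [representative()]
#' @exportClass ParetoFront
setClass("ParetoFront",
  representation(members = "list", objectives = "matrix",
                 spec = "ObjectiveSpec"))

setValidity("ParetoFront", function(object) {
  msg <- character()
  n <- length(object@members)
  if (n < 1L) msg <- c(msg, "a Pareto front cannot be empty")
  if (nrow(object@objectives) != n)
    msg <- c(msg, "objectives must have one row per member")
  if (ncol(object@objectives) != nObjectives(object@spec))
    msg <- c(msg, "objectives must have one column per objective in spec")
  if (n >= 2L) {
    idx <- paretoFilter(object@objectives, orientations(object@spec))
    if (length(idx) != n)
      msg <- c(msg, "members must be mutually non-dominated")
  }
  if (length(msg)) msg else TRUE
})

#' EvolutionConfig: parameters of an evolution run
#'
#' @slot nSubjects integer, subjects per dataset (even; default 3000).
#' @slot nSnps integer, SNPs per dataset.
#' @slot spec an [ObjectiveSpec-class].
#' @slot populationSize integer (default 1000).
#' @slot generations integer (default 2000).
#' @slot mutationRate per-genotype-entry mutation probability; `NA` selects a
#'   default that scales with sample size (0.004 at 500, 0.002 at 1000,
#'   0.001 at 3000 subjects).
#' @slot frontCap integer cap on survivors per generation; `NA` means
#'   unlimited. The constructor defaults to 100 when there are more than
#'   three objectives or the HWE objective is active, else unlimited.
#' @slot seed integer RNG seed (`NA`: use the current RNG state).
#' @slot resampleSame logical; if `TRUE` a mutation event draws uniformly
#'   over all three genotype states (so it may resample the current state and
#'   the effective rate is 2/3 of the nominal one). Default `FALSE`: a
#'   mutation always switches to one of the two other states.
#'
#' @seealso [evolutionConfig()], [evolve()]
#' @exportClass EvolutionConfig
setClass("EvolutionConfig",
  representation(nSubjects = "integer", nSnps = "integer",
                 spec = "ObjectiveSpec", populationSize = "integer",
                 generations = "integer", mutationRate = "numeric",
                 frontCap = "integer", seed = "integer",
                 resampleSame = "logical"))

setValidity("EvolutionConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 2L || object@nSubjects %% 2L != 0L)
    msg <- c(msg, "nSubjects must be a positive even number")
  if (object@populationSize < 1L) msg <- c(msg, "populationSize must be >= 1")
  if (object@generations < 0L) msg <- c(msg, "generations must be >= 0")
  if (is.na(object@mutationRate) || object@mutationRate < 0 ||
      object@mutationRate > 1)
    msg <- c(msg, "mutationRate must lie in [0, 1]")
  if (!is.na(object@frontCap) && object@frontCap < 1L)
    msg <- c(msg, "frontCap must be >= 1 (or NA for unlimited)")
  if (object@spec@maximizedOrder != object@nSnps)
    msg <- c(msg, "spec maximizedOrder must equal nSnps")
  if (length(msg)) msg else TRUE
})

#' EvolutionResult: the outcome of an evolution run
#'
#' @slot front the final [ParetoFront-class] (capped if a cap is configured).
#' @slot representativeIndex index into the front of the representative
#'   dataset (smallest Euclidean distance to the per-objective optima).
#' @slot history data.frame with one row per generation (0..generations):
#'   generation, front size before capping, and the best value over the
#'   front for each objective.
#' @slot config the [EvolutionConfig-class] that produced the run.
#'
#' @seealso [evolve()], [representative()], [writeFrontInfo()]
#' @exportClass EvolutionResult
setClass("EvolutionResult",
  representation(front = "ParetoFront", representativeIndex = "integer",
                 history = "data.frame", config = "EvolutionConfig"))

setValidity("EvolutionResult", function(object) {
  msg <- character()
  n <- length(object@front@members)
  i <- object@representativeIndex
  if (length(i) != 1L || is.na(i) || i < 1L || i > n)
    msg <- c(msg, "representativeIndex must point into the front")
  if (length(msg)) msg else TRUE
})

#' RandomSearchResult: the outcome of the random-search baseline
#'
#' @slot front the final [ParetoFront-class] over all sampled datasets.
#' @slot representativeIndex index of the representative front member.
#' @slot nDatasets integer, number of random datasets examined.
#' @slot nSubjects integer, subjects per dataset.
#' @slot seed integer RNG seed used (`NA` if none was set).
#'
#' @seealso [randomSearch()]
#' @exportClass RandomSearchResult
setClass("RandomSearchResult",
  representation(front = "ParetoFront", representativeIndex = "integer",
                 nDatasets = "numeric", nSubjects = "integer",
                 seed = "integer"))
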