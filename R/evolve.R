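#' Sample-size-scaled default mutation rate
#'
#' Rate calibration found 0.004 best for 500-subject and 0.002 best for
#' 1000-subject datasets, and extrapolated 0.001 for 3000 subjects; the
#' default picks the anchor nearest in log sample size.
#'
#' @param nSubjects number of subjects.
#' @return mutation probability per genotype entry.
#' @export
defaultMutationRate <- function(nSubjects) {
  anchors <- c(`500` = 0.004, `1000` = 0.002, `3000` = 0.001)
  sizes <- as.numeric(names(anchors))
  unname(anchors[which.min(abs(log(nSubjects) - log(sizes)))])
}

#' Create an EvolutionConfig
#'
#' Defaults follow the standard full-scale run: 3000 subjects, population
#' 1000, 2000 generations, mutation rate scaled to sample size
#' ([defaultMutationRate()]), and a survivor cap of 100 when more than three
#' objectives (or the HWE objective) are active, unlimited otherwise.
#'
#' @param nSnps number of SNPs `k`.
#' @param spec an [ObjectiveSpec-class]; default minimizes orders 1 and 2
#'   and maximizes order `k`.
#' @param nSubjects subjects per dataset (even).
#' @param populationSize datasets per generation.
#' @param generations number of generations.
#' @param mutationRate per-entry mutation probability (`NULL`: default).
#' @param frontCap survivor cap (`NULL`: automatic; `NA`: unlimited).
#' @param seed integer RNG seed (`NA`: use current RNG state).
#' @param resampleSame see [mutate()].
#' @return an [EvolutionConfig-class].
#' @examples
#' evolutionConfig(3, seed = 1)
#' evolutionConfig(5, spec = objectiveSpec(1:4, 5), seed = 1)
#' @export
evolutionConfig <- function(nSnps, spec = objectiveSpec(c(1, 2), nSnps),
                            nSubjects = 3000, populationSize = 1000,
                            generations = 2000, mutationRate = NULL,
                            frontCap = NULL, seed = NA, resampleSame = FALSE) {
  if (is.null(mutationRate)) mutationRate <- defaultMutationRate(nSubjects)
  if (is.null(frontCap)) {
    frontCap <- if (nObjectives(spec) > 3L || spec@hwe) 100L else NA_integer_
  }
  new("EvolutionConfig", nSubjects = as.integer(nSubjects),
      nSnps = as.integer(nSnps), spec = spec,
      populationSize = as.integer(populationSize),
      generations = as.integer(generations),
      mutationRate = as.numeric(mutationRate),
      frontCap = as.integer(frontCap), seed = as.integer(seed),
      resampleSame = isTRUE(resampleSame))
}

setMethod("show", "EvolutionConfig", function(object) {
  cat(sprintf(
    "EvolutionConfig: %d subjects x %d SNPs, pop %d, %d generations\n",
    object@nSubjects, object@nSnps, object@populationSize,
    object@generations))
  cat(sprintf("mutation rate %g, front cap %s, seed %s\n",
              object@mutationRate,
              ifelse(is.na(object@frontCap), "unlimited", object@frontCap),
              ifelse(is.na(object@seed), "<none>", object@seed)))
  show(object@spec)
})

#' Evolve a Pareto front of epistatic datasets
#'
#' Runs the mutation-only evolution strategy. Generation 0 is a population
#' of randomly initialized balanced datasets ([initCounts()]). Each
#' generation the population's Pareto-optimal datasets survive (capped at
#' the front "elbow" if a cap is configured, see [capFront()]), pass
#' unchanged into the next generation, and act as parents: the population is
#' refilled to size by mutated copies of the survivors, allocated round-robin
#' in stable order so every parent gets an equal share (plus one for the
#' first parents when the share does not divide evenly). Survivor objective
#' values are cached, never recomputed. After the final generation the front
#' is returned with its Euclidean-distance [representative()].
#'
#' @param config an [EvolutionConfig-class].
#' @param verbose print progress every 100 generations.
#' @return an [EvolutionResult-class].
#' @examples
#' cfg <- evolutionConfig(3, nSubjects = 200, populationSize = 50,
#'                        generations = 20, seed = 1)
#' res <- evolve(cfg)
#' representativeObjectives(res)
#' @export
evolve <- function(config, verbose = FALSE) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  spec <- config@spec
  k <- config@nSnps
  sense <- orientations(spec)
  P <- config@populationSize

  ctx <- objectiveContext(k, spec)
  pop <- initCountPopulation(config@nSubjects, k, P)
  obj <- populationObjectives(pop$case, pop$control, k, spec, ctx)  # d x P

  history <- vector("list", config@generations + 1L)
  frontIdx <- integer(0)

  for (gen in 0:config@generations) {
    frontIdx <- sort(cpp_stream_front(minimizedColumns(t(obj), sense)) + 1L)
    history[[gen + 1L]] <- c(
      generation = gen, frontSize = length(frontIdx),
      bestObjectiveValues(t(obj[, frontIdx, drop = FALSE]), sense))
    if (!is.na(config@frontCap) && length(frontIdx) > config@frontCap) {
      keep <- capFrontIndices(t(obj[, frontIdx, drop = FALSE]), sense,
                              config@frontCap)
      frontIdx <- frontIdx[keep]
    }
    nSurv <- length(frontIdx)
    if (nSurv > P)
      stop("Pareto front (", nSurv, ") exceeds the population size (", P,
           "); raise populationSize or configure a frontCap")
    if (gen == config@generations) break

    nOff <- P - nSurv
    parent <- frontIdx[rep_len(seq_len(nSurv), nOff)]
    offCase <- pop$case[, parent, drop = FALSE]
    offCtrl <- pop$control[, parent, drop = FALSE]
    if (nOff > 0L && config@mutationRate > 0) {
      m <- cpp_mutate_counts(offCase, offCtrl, k, config@mutationRate,
                             config@resampleSame)
      offCase <- m$case; offCtrl <- m$control
    }
    offObj <- if (nOff > 0L) {
      populationObjectives(offCase, offCtrl, k, spec, ctx)
    } else {
      obj[, 0, drop = FALSE]
    }
    pop <- list(case = cbind(pop$case[, frontIdx, drop = FALSE], offCase),
                control = cbind(pop$control[, frontIdx, drop = FALSE],
                                offCtrl))
    obj <- cbind(obj[, frontIdx, drop = FALSE], offObj)
    if (verbose && gen %% 100L == 0L)
      message(sprintf("generation %d: front %d, best %s", gen, nSurv,
                      paste(sprintf("%.4f", history[[gen + 1L]][-(1:2)]),
                            collapse = " ")))
  }

  members <- lapply(frontIdx, function(j)
    GenotypeCounts(pop$case[, j], pop$control[, j], k))
  front <- newParetoFront(members, t(obj[, frontIdx, drop = FALSE]), spec)
  repIdx <- representativeIndex(front@objectives, sense, spec@hwe)
  hist <- as.data.frame(do.call(rbind, history))
  new("EvolutionResult", front = front,
      representativeIndex = as.integer(repIdx), history = hist,
      config = config)
}

#' Result accessors
#'
#' `representative()` on a result returns the representative dataset;
#' `representativeObjectives()` its objective vector; `runHistory()` the
#' per-generation record (front size and per-objective best values).
#'
#' @param x an [EvolutionResult-class] or [RandomSearchResult-class].
#' @rdname representative
#' @export
setMethod("representative", "EvolutionResult",
          function(x) x@front@members[[x@representativeIndex]])

#' @rdname representative
#' @export
setMethod("representative", "RandomSearchResult",
          function(x) x@front@members[[x@representativeIndex]])

#' @rdname representative
#' @export
representativeObjectives <- function(x) {
  stopifnot(is(x, "EvolutionResult") || is(x, "RandomSearchResult"))
  x@front@objectives[x@representativeIndex, ]
}

#' @rdname representative
#' @export
runHistory <- function(x) {
  stopifnot(is(x, "EvolutionResult"))
  x@history
}

#' @rdname frontMembers
#' @export
setMethod("frontMembers", "EvolutionResult", function(x) x@front@members)

#' @rdname frontMembers
#' @export
setMethod("frontMembers", "RandomSearchResult", function(x) x@front@members)

#' @rdname frontMembers
#' @export
setMethod("objectiveMatrix", "EvolutionResult", function(x) x@front@objectives)

#' @rdname frontMembers
#' @export
setMethod("objectiveMatrix", "RandomSearchResult",
          function(x) x@front@objectives)

setMethod("show", "EvolutionResult", function(object) {
  cat(sprintf("EvolutionResult: %d generations, final front %d datasets\n",
              object@config@generations, length(object@front@members)))
  v <- representativeObjectives(object)
  cat("representative:", paste(sprintf("%s=%.4g", names(v), v),
                               collapse = " "), "\n")
})

setMethod("show", "RandomSearchResult", function(object) {
  cat(sprintf("RandomSearchResult: %g datasets, front %d datasets\n",
              object@nDatasets, length(object@front@members)))
  v <- representativeObjectives(object)
  cat("representative:", paste(sprintf("%s=%.4g", names(v), v),
                               collapse = " "), "\n")
})

#' Sweep mutation rates
#'
#' Runs [evolve()] at each rate with `replicates` independent runs and
#' reports the mean and standard deviation of the representative's
#' maximized-order (full-order) MDR accuracy, ranked best first. This is the
#' calibration design used to pick a working rate for a given sample size:
#' a fixed generation budget reveals which rate makes the most progress.
#'
#' @param rates mutation probabilities to evaluate.
#' @param nSnps,spec,nSubjects,populationSize,generations,frontCap,resampleSame
#'   as in [evolutionConfig()].
#' @param replicates independent runs per rate.
#' @param seed integer seed for the whole sweep (`NA`: current RNG state).
#' @return data.frame with columns `rate`, `meanAccuracy`, `sdAccuracy`,
#'   `rank` (1 = best mean), plus an `"accuracies"` attribute holding the
#'   per-run representative accuracies (rates x replicates).
#' @export
sweepMutationRates <- function(rates, nSnps,
                               spec = objectiveSpec(c(1, 2), nSnps),
                               nSubjects = 500, populationSize = 1000,
                               generations = 750, replicates = 1,
                               frontCap = NULL, seed = NA,
                               resampleSame = FALSE) {
  stopifnot(length(rates) >= 1, replicates >= 1)
  if (!is.na(seed)) set.seed(seed)
  full <- paste0("acc", nSnps)
  acc <- matrix(NA_real_, length(rates), replicates)
  for (i in seq_along(rates)) {
    for (r in seq_len(replicates)) {
      cfg <- evolutionConfig(nSnps, spec = spec, nSubjects = nSubjects,
                             populationSize = populationSize,
                             generations = generations,
                             mutationRate = rates[i], frontCap = frontCap,
                             seed = NA, resampleSame = resampleSame)
      acc[i, r] <- representativeObjectives(evolve(cfg))[[full]]
    }
  }
  out <- data.frame(rate = rates, meanAccuracy = rowMeans(acc),
                    sdAccuracy = apply(acc, 1, sd))
  out$rank <- rank(-out$meanAccuracy, ties.method = "first")
  attr(out, "accuracies") <- acc
  out
}
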