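#' Random-search baseline
#'
#' Generates `nDatasets` random balanced datasets and keeps their Pareto
#' front in a streaming archive, so memory is bounded by the front size, not
#' by `nDatasets`. By default each dataset is drawn at the count level: the
#' per-class cell counts follow a multinomial over the `3^k` genotype-cell
#' probabilities implied by independent SNPs at initialization frequencies —
#' exactly the distribution obtained by tabulating a random genotype matrix
#' (`method = "matrix"` keeps the explicit matrix path for validation).
#'
#' @param nDatasets number of random datasets to examine (`>= 1`).
#' @param nSnps number of SNPs `k`.
#' @param spec an [ObjectiveSpec-class]; default minimizes orders 1 and 2.
#' @param nSubjects subjects per dataset (even; default 3000).
#' @param seed integer RNG seed (`NA`: current RNG state).
#' @param method `"counts"` (fast, default) or `"matrix"` (explicit
#'   subject-level generation; identical distribution).
#' @param chunkSize datasets generated per streaming batch.
#' @return a [RandomSearchResult-class] holding the final front and its
#'   [representative()].
#' @examples
#' res <- randomSearch(2000, 3, nSubjects = 200, seed = 1)
#' representativeObjectives(res)
#' @export
randomSearch <- function(nDatasets, nSnps,
                         spec = objectiveSpec(c(1, 2), nSnps),
                         nSubjects = 3000, seed = NA,
                         method = c("counts", "matrix"),
                         chunkSize = 100000L) {
  stopifnot(nDatasets >= 1)
  method <- match.arg(method)
  if (!is.na(seed)) set.seed(seed)
  k <- as.integer(nSnps)
  sense <- orientations(spec)
  p <- cellProbabilities(k)

  ctx <- objectiveContext(k, spec)
  archCase <- archCtrl <- matrix(0L, 3L^k, 0L)
  archObj <- matrix(0, nObjectives(spec), 0L)

  remaining <- nDatasets
  while (remaining > 0) {
    m <- as.integer(min(chunkSize, remaining))
    remaining <- remaining - m
    if (method == "counts") {
      ca <- rmultinom(m, nSubjects / 2, p)
      co <- rmultinom(m, nSubjects / 2, p)
    } else {
      tabs <- replicate(m, asCounts(initDataset(nSubjects, k)),
                        simplify = FALSE)
      ca <- vapply(tabs, caseCounts, integer(3L^k))
      co <- vapply(tabs, controlCounts, integer(3L^k))
    }
    obj <- populationObjectives(ca, co, k, spec, ctx)
    keep <- cpp_stream_front(minimizedColumns(t(cbind(archObj, obj)),
                                              sense)) + 1L
    keep <- sort(keep)
    nArch <- ncol(archObj)
    old <- keep[keep <= nArch]
    new <- keep[keep > nArch] - nArch
    archCase <- cbind(archCase[, old, drop = FALSE],
                      ca[, new, drop = FALSE])
    archCtrl <- cbind(archCtrl[, old, drop = FALSE],
                      co[, new, drop = FALSE])
    archObj <- cbind(archObj[, old, drop = FALSE],
                     obj[, new, drop = FALSE])
  }

  members <- lapply(seq_len(ncol(archObj)), function(j)
    GenotypeCounts(archCase[, j], archCtrl[, j], k))
  front <- newParetoFront(members, t(archObj), spec)
  repIdx <- representativeIndex(front@objectives, sense, spec@hwe)
  new("RandomSearchResult", front = front,
      representativeIndex = as.integer(repIdx),
      nDatasets = as.numeric(nDatasets), nSubjects = as.integer(nSubjects),
      seed = as.integer(seed))
}
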