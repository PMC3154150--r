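#' @rdname nSubjects
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname nSnps
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname caseCounts
#' @export
setGeneric("caseCounts", function(x) standardGeneric("caseCounts"))

#' @rdname caseCounts
#' @export
setGeneric("controlCounts", function(x) standardGeneric("controlCounts"))

#' @rdname genotypes
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname genotypes
#' @export
setGeneric("status", function(x) standardGeneric("status"))

#' Convert between subject-level and contingency representations
#'
#' `asCounts()` collapses a [GenotypeDataset-class] to its per-class
#' genotype-cell counts; `asDataset()` expands counts back to a subject
#' matrix in the canonical order (cases before controls, subjects sorted by
#' cell index). The round trip preserves the contingency table exactly; it
#' does not preserve subject identity, which carries no information here.
#'
#' @param x a [GenotypeDataset-class] or [GenotypeCounts-class].
#' @return `asCounts()`: a [GenotypeCounts-class]; `asDataset()`: a
#'   [GenotypeDataset-class].
#' @examples
#' d <- initDataset(20, 3)
#' asDataset(asCounts(d))
#' @rdname asCounts
#' @export
setGeneric("asCounts", function(x) standardGeneric("asCounts"))

#' @rdname asCounts
#' @export
setGeneric("asDataset", function(x) standardGeneric("asDataset"))

#' @rdname mutate
#' @export
setGeneric("mutate", function(x, rate, ...) standardGeneric("mutate"))

#' @rdname mdrAccuracy
#' @export
setGeneric("mdrAccuracy", function(x, subset) standardGeneric("mdrAccuracy"))

#' @rdname maxOrderAccuracy
#' @export
setGeneric("maxOrderAccuracy",
           function(x, order) standardGeneric("maxOrderAccuracy"))

#' @rdname hweChiSquare
#' @export
setGeneric("hweChiSquare",
           function(x, snp, pooled = TRUE) standardGeneric("hweChiSquare"))

#' @rdname evaluateObjectives
#' @export
setGeneric("evaluateObjectives",
           function(x, spec) standardGeneric("evaluateObjectives"))

#' @rdname capFront
#' @export
setGeneric("capFront", function(front, cap) standardGeneric("capFront"))

#' @rdname representative
#' @export
setGeneric("representative", function(x) standardGeneric("representative"))

#' @rdname frontMembers
#' @export
setGeneric("frontMembers", function(x) standardGeneric("frontMembers"))

#' @rdname frontMembers
#' @export
setGeneric("objectiveMatrix", function(x) standardGeneric("objectiveMatrix"))

#' @rdname writeDataset
#' @export
setGeneric("writeDataset", function(x, file) standardGeneric("writeDataset"))

#' @rdname writeFrontInfo
#' @export
setGeneric("writeFrontInfo",
           function(x, dir, saveFront = FALSE) standardGeneric("writeFrontInfo"))
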