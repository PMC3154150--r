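# sign-normalize an objectives matrix (rows = members) so that every
# objective is minimized; returns d x n matrix for the C++ kernels
minimizedColumns <- function(objectives, orientations) {
  obj <- t(as.matrix(objectives))
  if (nrow(obj) != length(orientations))
    stop("orientations must have one entry per objective")
  flip <- orientations == "max"
  obj[flip, ] <- -obj[flip, , drop = FALSE]
  obj
}

#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` when it is at least as good in every objective
#' (respecting each objective's orientation) and strictly better in at least
#' one. Equal vectors do not dominate each other, so dominance is a strict
#' partial order.
#'
#' @param a,b numeric objective vectors of equal length.
#' @param orientations character vector of `"min"`/`"max"` per objective.
#' @return logical.
#' @examples
#' dominates(c(0.50, 0.90), c(0.51, 0.80), c("min", "max"))
#' @export
dominates <- function(a, b, orientations) {
  if (length(a) != length(b) || length(a) != length(orientations))
    stop("objective vectors and orientations must have matching lengths")
  s <- ifelse(orientations == "max", -1, 1)
  a <- s * a; b <- s * b
  all(a <= b) && any(a < b)
}

#' Non-dominated members of a set of objective vectors
#'
#' Returns the indices of exactly those rows not dominated by any other row.
#' Members with identical objective vectors are all retained (they are
#' distinct datasets with equal scores).
#'
#' @param objectives numeric matrix, one row per member.
#' @param orientations character vector of `"min"`/`"max"` per objective.
#' @return integer vector of row indices, in input order.
#' @examples
#' m <- rbind(c(0.51, 0.80), c(0.50, 0.70), c(0.52, 0.90), c(0.51, 0.60))
#' paretoFilter(m, c("min", "max"))  # 1, 2, 3
#' @export
paretoFilter <- function(objectives, orientations) {
  objectives <- rbind(objectives)
  if (nrow(objectives) < 1L)
    stop("paretoFilter requires at least one objective vector")
  which(cpp_nondominated(minimizedColumns(objectives, orientations)))
}

# internal constructor for validated fronts
newParetoFront <- function(members, objectives, spec) {
  colnames(objectives) <- objectiveNames(spec)
  new("ParetoFront", members = members, objectives = objectives, spec = spec)
}

#' Build a ParetoFront from candidate datasets
#'
#' Evaluates every candidate under `spec` and keeps the non-dominated ones.
#'
#' @param members list of [GenotypeCounts-class] (or
#'   [GenotypeDataset-class]) objects.
#' @param spec an [ObjectiveSpec-class].
#' @return a [ParetoFront-class].
#' @export
paretoFront <- function(members, spec) {
  members <- lapply(members, asCounts)
  obj <- t(vapply(members, function(m) evaluateObjectives(m, spec),
                  numeric(nObjectives(spec))))
  keep <- paretoFilter(obj, orientations(spec))
  newParetoFront(members[keep], obj[keep, , drop = FALSE], spec)
}

#' Front accessors
#'
#' `frontMembers()` returns the list of member datasets, `objectiveMatrix()`
#' the member-by-objective score matrix.
#'
#' @param x a [ParetoFront-class], [EvolutionResult-class] or
#'   [RandomSearchResult-class].
#' @return list / numeric matrix.
#' @rdname frontMembers
#' @export
setMethod("frontMembers", "ParetoFront", function(x) x@members)

#' @rdname frontMembers
#' @export
setMethod("objectiveMatrix", "ParetoFront", function(x) x@objectives)

setMethod("length", "ParetoFront", function(x) length(x@members))

setMethod("show", "ParetoFront", function(object) {
  o <- orientations(object@spec)
  cat(sprintf("ParetoFront with %d datasets\n", length(object@members)))
  cat("objectives:",
      paste0(ifelse(o == "min", "↓", "↑"), colnames(object@objectives),
             collapse = " "), "\n")
  best <- bestObjectiveValues(object@objectives, o)
  cat("best values:", paste(sprintf("%s=%.4g", names(best), best),
                            collapse = " "), "\n")
})

# per-objective optimum over the front
bestObjectiveValues <- function(objectives, orientations) {
  best <- numeric(length(orientations))
  for (i in seq_along(orientations)) {
    best[i] <- if (orientations[i] == "max") max(objectives[, i])
    else min(objectives[, i])
  }
  setNames(best, colnames(objectives))
}

# min-max normalize member scores to [0, 1] with 0 = best per objective
normalizedScores <- function(objectives, orientations) {
  norm <- matrix(0, nrow(objectives), ncol(objectives))
  for (i in seq_along(orientations)) {
    v <- objectives[, i]
    rng <- max(v) - min(v)
    if (rng > 0) {
      norm[, i] <- if (orientations[i] == "max") (max(v) - v) / rng
      else (v - min(v)) / rng
    }
  }
  norm
}

#' Cap a Pareto front at its "elbow"
#'
#' When a front exceeds `cap` members, keeps the `cap` members with the
#' smallest Euclidean distance to the front's ideal point after per-objective
#' min-max normalization to \[0, 1\] (0 = best). This retains individuals
#' that are good in several objectives at once at the cost of those that
#' excel in a single one; ties break by stable input order. Fronts at or
#' under the cap are returned unchanged.
#'
#' @param front a [ParetoFront-class].
#' @param cap maximum number of members (`>= 1`).
#' @return a [ParetoFront-class] with at most `cap` members.
#' @rdname capFront
#' @export
setMethod("capFront", "ParetoFront", function(front, cap) {
  keep <- capFrontIndices(front@objectives, orientations(front@spec), cap)
  if (length(keep) == length(front@members)) return(front)
  newParetoFront(front@members[keep],
                 front@objectives[keep, , drop = FALSE], front@spec)
})

capFrontIndices <- function(objectives, orientations, cap) {
  stopifnot(cap >= 1)
  n <- nrow(objectives)
  if (n <= cap) return(seq_len(n))
  d <- sqrt(rowSums(normalizedScores(objectives, orientations)^2))
  sort(order(d)[seq_len(cap)])
}

#' Representative dataset of a Pareto front
#'
#' The single front member summarizing a run: the one with the smallest
#' Euclidean distance from the vector of per-objective optima achieved by
#' the front. When every objective is an MDR accuracy the distance is taken
#' on the raw accuracy scale (all commensurate, in \[0.5, 1\]); when an HWE
#' chi-square objective is present all objectives are min-max normalized
#' over the front first, since the unbounded chi-square would otherwise
#' dominate the distance. Ties break by stable member order.
#'
#' @param x a [ParetoFront-class], [EvolutionResult-class] or
#'   [RandomSearchResult-class].
#' @return for a front, the index of the representative member; for results,
#'   the representative [GenotypeCounts-class] itself (see
#'   [representativeObjectives()]).
#' @rdname representative
#' @export
setMethod("representative", "ParetoFront", function(x) {
  representativeIndex(x@objectives, orientations(x@spec), x@spec@hwe)
})

representativeIndex <- function(objectives, orientations, normalize) {
  if (normalize) {
    d <- rowSums(normalizedScores(objectives, orientations)^2)
  } else {
    best <- bestObjectiveValues(objectives, orientations)
    d <- rowSums((objectives - rep(best, each = nrow(objectives)))^2)
  }
  which.min(d)
}
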