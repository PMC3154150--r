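#' Write a dataset in the MDR flat-file format
#'
#' Tab-delimited text with a header row `X1 .. Xk Class`, one row per
#' subject, genotypes coded 0/1/2 and class 1 (case) / 0 (control) — the
#' format consumed by MDR tooling. Subjects are written in the canonical
#' deterministic order: cases before controls, each class sorted by genotype
#' cell index (the contingency representation carries no subject identity,
#' so any fixed order is equivalent).
#'
#' @param x a [GenotypeDataset-class] or [GenotypeCounts-class].
#' @param file output path or connection.
#' @return `file`, invisibly.
#' @rdname writeDataset
#' @export
setMethod("writeDataset", "GenotypeCounts", function(x, file) {
  writeDataset(asDataset(x), file)
})

#' @rdname writeDataset
#' @export
setMethod("writeDataset", "GenotypeDataset", function(x, file) {
  x <- asDataset(asCounts(x))  # canonical subject order
  df <- as.data.frame(x@genotypes)
  names(df) <- paste0("X", seq_len(ncol(df)))
  df$Class <- x@status
  ok <- tryCatch({
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e)
    stop("failed to write dataset to '", file, "': ", conditionMessage(e),
         call. = FALSE))
  invisible(file)
})

#' Read a dataset from the MDR flat-file format
#'
#' Strict by default: the header must be exactly `X1 .. Xk` followed by
#' `Class`, fields tab-separated, genotypes in \{0, 1, 2\}, class in
#' \{0, 1\}, and the design balanced. Malformed entries are reported with
#' their line number. With `lenient = TRUE` the columns may appear in any
#' order (the class column is identified by the name `Class`) and any
#' whitespace separates fields.
#'
#' @param file input path or connection.
#' @param lenient accept permuted header order and general whitespace.
#' @return a [GenotypeDataset-class].
#' @export
readDataset <- function(file, lenient = FALSE) {
  sep <- if (lenient) "" else "\t"
  df <- tryCatch(
    read.table(file, header = TRUE, sep = sep, check.names = FALSE,
               colClasses = "integer"),
    error = function(e)
      stop("failed to read dataset from '", file, "': ",
           conditionMessage(e), call. = FALSE))
  k <- ncol(df) - 1L
  if (k < 1L || !"Class" %in% names(df))
    stop("'", file, "': expected genotype columns plus a 'Class' column")
  expected <- c(paste0("X", seq_len(k)), "Class")
  if (!lenient && !identical(names(df), expected))
    stop("'", file, "': strict dialect requires header '",
         paste(expected, collapse = " "),
         "' (use lenient = TRUE for permuted columns)")
  if (lenient) {
    geno <- df[, setdiff(names(df), "Class"), drop = FALSE]
  } else {
    geno <- df[, seq_len(k), drop = FALSE]
  }
  cls <- df$Class
  gm <- as.matrix(geno)
  badG <- which(matrix(!(gm %in% c(0L, 1L, 2L)), nrow(gm)), arr.ind = TRUE)
  if (nrow(badG))
    stop("'", file, "': genotype value ", gm[badG[1, , drop = FALSE]],
         " outside {0,1,2} at line ", badG[1, 1] + 1L,
         " (column ", names(geno)[badG[1, 2]], ")")
  badC <- which(!cls %in% c(0L, 1L))
  if (length(badC))
    stop("'", file, "': class value ", cls[badC[1]],
         " outside {0,1} at line ", badC[1] + 1L)
  if (sum(cls == 1L) != sum(cls == 0L))
    stop("'", file, "': unbalanced design (", sum(cls == 1L), " cases vs ",
         sum(cls == 0L), " controls)")
  GenotypeDataset(as.matrix(geno), cls)
}

#' Export a run: datasets, front information and configuration echo
#'
#' Writes a run directory in the layout of the public dataset archives: the
#' representative dataset (`representative.txt`), optionally every front
#' dataset (`front/dataset_<i>.txt`), a tab-delimited `front_info.tsv` with
#' one record per front member (dataset filename, every objective value and
#' a representative flag) enabling downstream filtering, and a
#' machine-readable `run_config.json` echoing all parameters and the seed.
#'
#' @param x an [EvolutionResult-class] or [RandomSearchResult-class].
#' @param dir output directory (created if needed).
#' @param saveFront also write every front dataset file (fronts can hold
#'   ~100 datasets; the representative is always saved).
#' @return `dir`, invisibly.
#' @rdname writeFrontInfo
#' @export
setMethod("writeFrontInfo", "EvolutionResult",
          function(x, dir, saveFront = FALSE) {
  cfg <- x@config
  echo <- list(
    type = "evolution", nSubjects = cfg@nSubjects, nSnps = cfg@nSnps,
    minimizedOrders = cfg@spec@minimizedOrders,
    maximizedOrder = cfg@spec@maximizedOrder, hwe = cfg@spec@hwe,
    hweAggregate = cfg@spec@hweAggregate, hwePooled = cfg@spec@hwePooled,
    populationSize = cfg@populationSize, generations = cfg@generations,
    mutationRate = cfg@mutationRate, frontCap = cfg@frontCap,
    resampleSame = cfg@resampleSame, seed = cfg@seed,
    representativeScale = if (cfg@spec@hwe) "normalized" else "raw")
  .writeRunDir(x@front, x@representativeIndex, echo, dir, saveFront)
  hist <- x@history
  write.table(hist, file.path(dir, "history.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
})

#' @rdname writeFrontInfo
#' @export
setMethod("writeFrontInfo", "RandomSearchResult",
          function(x, dir, saveFront = FALSE) {
  spec <- x@front@spec
  echo <- list(
    type = "randomSearch", nSubjects = x@nSubjects,
    nSnps = spec@maximizedOrder, minimizedOrders = spec@minimizedOrders,
    maximizedOrder = spec@maximizedOrder, hwe = spec@hwe,
    hweAggregate = spec@hweAggregate, hwePooled = spec@hwePooled,
    nDatasets = x@nDatasets, seed = x@seed,
    representativeScale = if (spec@hwe) "normalized" else "raw")
  .writeRunDir(x@front, x@representativeIndex, echo, dir, saveFront)
  invisible(dir)
})

.writeRunDir <- function(front, repIdx, configEcho, dir, saveFront) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(front@members)
  files <- sprintf("front/dataset_%03d.txt", seq_len(n))
  files[repIdx] <- "representative.txt"
  info <- data.frame(dataset = files, front@objectives,
                     representative = seq_len(n) == repIdx,
                     check.names = FALSE)
  write.table(info, file.path(dir, "front_info.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(configEcho, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeDataset(front@members[[repIdx]], file.path(dir, "representative.txt"))
  if (saveFront) {
    dir.create(file.path(dir, "front"), showWarnings = FALSE)
    for (i in setdiff(seq_len(n), repIdx))
      writeDataset(front@members[[i]], file.path(dir, files[i]))
  }
  invisible(dir)
}
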