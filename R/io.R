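#' Read and write count matrices, sample sheets and result tables
#'
#' Counts travel as TSV (a `gene_id` column plus one column per sample)
#' or MatrixMarket (`.mtx` plus `.rownames`/`.colnames` index files);
#' the sample sheet is a TSV with columns `sample_id`, `condition`.
#'
#' @param object a [DGECountSet-class].
#' @param path file path (for MatrixMarket, the `.mtx` path; the index
#'   files sit next to it).
#' @return `readCounts*` return a [DGECountSet-class]; writers return the
#'   path invisibly.
#' @name counts-io
NULL

#' @rdname counts-io
#' @export
writeCountsTSV <- function(object, path) {
  cts <- assay(object, "counts")
  df <- data.frame(gene_id = rownames(cts), cts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts-io
#' @param sample_sheet path to the sample sheet TSV.
#' @export
readCountsTSV <- function(path, sample_sheet) {
  df <- read.delim(path, check.names = FALSE)
  cts <- as.matrix(df[, -1, drop = FALSE])
  rownames(cts) <- df$gene_id
  ss <- read.delim(sample_sheet)
  idx <- match(colnames(cts), ss$sample_id)
  if (anyNA(idx)) stop("sample sheet does not cover all samples")
  DGECountSet(cts, condition = ss$condition[idx])
}

#' @rdname counts-io
#' @export
writeCountsMM <- function(object, path) {
  cts <- assay(object, "counts")
  Matrix::writeMM(Matrix::Matrix(cts, sparse = TRUE), path)
  writeLines(rownames(cts), paste0(path, ".rownames"))
  writeLines(colnames(cts), paste0(path, ".colnames"))
  invisible(path)
}

#' @rdname counts-io
#' @export
readCountsMM <- function(path, sample_sheet) {
  cts <- as.matrix(Matrix::readMM(path))
  rownames(cts) <- readLines(paste0(path, ".rownames"))
  colnames(cts) <- readLines(paste0(path, ".colnames"))
  ss <- read.delim(sample_sheet)
  idx <- match(colnames(cts), ss$sample_id)
  if (anyNA(idx)) stop("sample sheet does not cover all samples")
  DGECountSet(cts, condition = ss$condition[idx])
}

#' @rdname counts-io
#' @export
writeSampleSheet <- function(object, path) {
  write.table(data.frame(sample_id = colnames(object),
                         condition = as.character(condition(object))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts-io
#' @export
writeTruthTable <- function(object, path) {
  tt <- truthTable(object)
  if (is.null(tt)) stop("object carries no ground truth")
  write.table(tt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an engine result as TSV
#'
#' Columns: gene_id, base_mean, log2fc, p_value, posterior_de,
#' p_adjusted, filtered.
#'
#' @param result an [EngineResult-class].
#' @param path output path.
#' @export
writeEngineResult <- function(result, path) {
  write.table(resultTable(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write normalization factors as TSV (sample_id, method, factor)
#' @param factors data.frame from a factor function.
#' @param path output path.
#' @export
writeNormFactors <- function(factors, path) {
  write.table(factors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a concordance report as TSV (region, count)
#' @param report list from [concordance()].
#' @param path output path.
#' @export
writeConcordance <- function(report, path) {
  write.table(report$regions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
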