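#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowData colData rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' DGECountSet: a two-condition count matrix
#'
#' `DGECountSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"counts"` assay of non-negative integers and a mandatory
#' two-level `condition` factor in `colData`.  When the object comes from
#' the simulator, `rowData` carries the ground truth (`isDE`,
#' `trueLog2FC`) and `metadata()` the simulation parameters.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("DGECountSet", contains = "SummarizedExperiment")

setValidity("DGECountSet", function(object) {
  msg <- NULL
  if (!("counts" %in% names(assays(object))))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (!("condition" %in% names(colData(object))))
    msg <- c(msg, "colData column 'condition' is required")
  else {
    cond <- colData(object)$condition
    if (!is.factor(cond) || nlevels(cond) != 2L)
      msg <- c(msg, "'condition' must be a factor with exactly two levels")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DGECountSet
#'
#' @param counts gene x sample matrix of non-negative integers with
#'   rownames (gene ids) and colnames (sample ids).
#' @param condition per-sample condition labels (coerced to a two-level
#'   factor; the first level is treated as the reference/control group).
#' @param truth optional data.frame with columns `gene_id`, `is_de`,
#'   `true_log2fc` (simulation ground truth), matched to rows by gene id.
#' @param metadata optional list stored in `metadata()`.
#' @return a [DGECountSet-class] object.
#' @examples
#' cts <- matrix(rpois(40, 10), 10, 4,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' dcs <- DGECountSet(cts, condition = c("A", "A", "B", "B"))
#' condition(dcs)
#' @export
DGECountSet <- function(counts, condition, truth = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  .assertCounts(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample_%03d", seq_len(ncol(counts)))
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts))
    stop("'condition' must have one entry per sample")
  cd <- DataFrame(condition = condition, row.names = colnames(counts))
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(truth)) {
    idx <- match(rownames(counts), truth$gene_id)
    if (anyNA(idx)) stop("truth table does not cover all gene ids")
    rd$isDE <- as.logical(truth$is_de[idx])
    rd$trueLog2FC <- as.numeric(truth$true_log2fc[idx])
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd,
                             metadata = metadata)
  new("DGECountSet", se)
}

#' @describeIn DGECountSet accessor for the condition factor.
#' @param object,x a `DGECountSet`.
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname DGECountSet
#' @export
setMethod("condition", "DGECountSet", function(object)
  colData(object)$condition)

#' @describeIn DGECountSet ground-truth table (`NULL` when the object does
#'   not come from the simulator).
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))

#' @rdname DGECountSet
#' @export
setMethod("truthTable", "DGECountSet", function(object) {
  rd <- rowData(object)
  if (!("isDE" %in% names(rd))) return(NULL)
  data.frame(gene_id = rownames(object),
             is_de = rd$isDE,
             true_log2fc = rd$trueLog2FC,
             row.names = NULL)
})

setMethod("show", "DGECountSet", function(object) {
  cat("DGECountSet:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("condition: ",
      paste(sprintf("%s (n=%d)", levels(condition(object)),
                    tabulate(condition(object))), collapse = " vs "), "\n")
  if (!is.null(truthTable(object)))
    cat("ground truth:", sum(rowData(object)$isDE), "DE genes\n")
})

#' EngineResult: per-gene output of a DGE engine
#'
#' Holds one row per gene: mean normalized count, log2 fold change
#' (second condition level over the first, with pseudocount), and either a
#' p-value (with BH adjustment) or a posterior probability of differential
#' expression, depending on the engine family.  Genes removed by the
#' engine's low-count filter keep their fold change but carry `NA`
#' p-values/posteriors and `filtered = TRUE`.
#'
#' @slot engine engine name.
#' @slot table data.frame with columns `gene_id`, `base_mean`, `log2fc`,
#'   `p_value`, `posterior_de`, `p_adjusted`, `filtered`.
#' @slot params list of parameters the engine ran with.
#' @export
setClass("EngineResult",
         representation(engine = "character", table = "data.frame",
                        params = "list"))

setValidity("EngineResult", function(object) {
  tab <- object@table
  need <- c("gene_id", "base_mean", "log2fc", "p_value", "posterior_de",
            "p_adjusted", "filtered")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$gene_id)) return("duplicate gene ids")
  p <- tab$p_value; q <- tab$posterior_de
  if (any(!is.na(p) & !is.na(q)))
    return("a gene may carry a p-value or a posterior, not both")
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p-values outside [0,1]")
  if (any(q < 0 | q > 1, na.rm = TRUE)) return("posteriors outside [0,1]")
  if (any(tab$filtered & (!is.na(p) | !is.na(q))))
    return("filtered genes must carry no p-value/posterior")
  TRUE
})

EngineResult <- function(engine, table, params = list()) {
  new("EngineResult", engine = engine,
      table = as.data.frame(table), params = params)
}

#' @describeIn EngineResult the per-gene result table.
#' @param object an `EngineResult`.
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname EngineResult
#' @export
setMethod("resultTable", "EngineResult", function(object) object@table)

#' @describeIn EngineResult the engine name.
#' @export
setGeneric("engineName", function(object) standardGeneric("engineName"))

#' @rdname EngineResult
#' @export
setMethod("engineName", "EngineResult", function(object) object@engine)

setMethod("show", "EngineResult", function(object) {
  tab <- object@table
  cat("EngineResult <", object@engine, ">: ", nrow(tab), " genes, ",
      sum(tab$filtered), " filtered\n", sep = "")
  mode <- if (any(!is.na(tab$p_value))) "p-values" else "posteriors"
  cat("score mode:", mode, "\n")
})

#' DEGSet: a called set of differentially expressed genes
#'
#' @slot engine engine name the call came from.
#' @slot f subsampling fraction of the underlying counts.
#' @slot r iteration index.
#' @slot regime `"no_fold"` or `"two_fold"` filtering regime.
#' @slot geneIds character vector of gene ids in the set.
#' @export
setClass("DEGSet",
         representation(engine = "character", f = "numeric", r = "integer",
                        regime = "character", geneIds = "character"))

setValidity("DEGSet", function(object) {
  if (!object@regime %in% c("no_fold", "two_fold"))
    return("regime must be 'no_fold' or 'two_fold'")
  if (anyDuplicated(object@geneIds)) return("duplicate gene ids")
  TRUE
})

DEGSet <- function(engine, geneIds, f = 1, r = 1L, regime = "no_fold") {
  new("DEGSet", engine = engine, f = as.numeric(f), r = as.integer(r),
      regime = regime, geneIds = as.character(geneIds))
}

#' @describeIn DEGSet gene ids in the set.
#' @param object a `DEGSet`.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname DEGSet
#' @export
setMethod("geneIds", "DEGSet", function(object) object@geneIds)

setMethod("show", "DEGSet", function(object) {
  cat("DEGSet <", object@engine, "> f=", object@f, " r=", object@r,
      " regime=", object@regime, ": ", length(object@geneIds), " genes\n",
      sep = "")
})

#' FriedmanResult: tie-corrected Friedman rank test
#'
#' @slot statistic tie-corrected chi-squared statistic.
#' @slot df degrees of freedom (treatments - 1).
#' @slot p.value upper-tail chi-squared probability.
#' @slot meanRanks average rank per treatment across blocks.
#' @slot rankMatrix blocks x treatments matrix of within-block ranks
#'   (average ranks for ties).
#' @slot tieCorrected always `TRUE`; the statistic reduces to the classic
#'   one when no ties occur.
#' @export
setClass("FriedmanResult",
         representation(statistic = "numeric", df = "integer",
                        p.value = "numeric", meanRanks = "numeric",
                        rankMatrix = "matrix", tieCorrected = "logical"))

setMethod("show", "FriedmanResult", function(object) {
  cat("Friedman rank test (tie-corrected)\n")
  cat(sprintf("  chi-squared = %.4f, df = %d, p = %.4g\n",
              object@statistic, object@df, object@p.value))
  cat("  mean ranks:\n")
  print(round(object@meanRanks, 3))
})

#' PosthocMatrix: pairwise post-hoc p-values after a Friedman test
#'
#' @slot method `"conover"` or `"nemenyi"`.
#' @slot p.matrix symmetric matrix of two-sided p-values (`NA` diagonal).
#' @slot degenerate logical; `TRUE` when the Conover pooled-variance
#'   denominator is exactly zero (identical rankings in every block), in
#'   which case off-diagonal p-values of unequal rank sums are reported
#'   as 0 and flagged here rather than silently.
#' @export
setClass("PosthocMatrix",
         representation(method = "character", p.matrix = "matrix",
                        degenerate = "logical"))

#' @describeIn PosthocMatrix the pairwise p-value matrix.
#' @param object a `PosthocMatrix`.
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname PosthocMatrix
#' @export
setMethod("pValues", "PosthocMatrix", function(object) object@p.matrix)

setMethod("show", "PosthocMatrix", function(object) {
  cat("Post-hoc pairwise comparisons (", object@method, ")\n", sep = "")
  if (object@degenerate)
    cat("  [degenerate: identical rankings in every block]\n")
  print(signif(object@p.matrix, 3))
})
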