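#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor cutree hclust as.dist p.adjust phyper pt qt runif
#'   rnorm rbinom sd quantile
#' @importFrom utils head read.delim write.table
NULL

#' Cohort of brain expression profiles with sample metadata
#'
#' `AgingCohort` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' to hold a transcripts-by-samples matrix of normalized (log-scale)
#' expression together with the per-sample metadata this pipeline needs:
#' donor age in years, sex, RNA integrity number (RIN), post-mortem interval
#' (PMI, hours), sequencing batch, and the per-sample mean and standard
#' deviation of intronic background expression used by the detection filter.
#'
#' The single assay is named `"expr"`. Optional transcript-to-gene annotation
#' lives in `rowData(x)$gene_symbol`.
#'
#' @section Validity:
#' Transcript and sample identifiers must be unique and non-empty; all
#' expression values finite; at least 2 transcripts and 3 samples; ages
#' strictly positive; RIN within 0-10; PMI non-negative; intronic SD
#' non-negative; sex limited to `"female"`/`"male"`.
#'
#' @seealso [AgingCohort()] for construction, [filterDetected()],
#'   [collapseToGene()], [buildNetwork()]
#' @name AgingCohort-class
#' @aliases AgingCohort-class
#' @exportClass AgingCohort
setClass("AgingCohort", contains = "SummarizedExperiment")

.REQUIRED_META <- c("age", "sex", "rin", "pmi", "batch",
                    "intronic_mean", "intronic_sd")

setValidity("AgingCohort", function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'expr' is required")
  m <- SummarizedExperiment::assay(object, "expr")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "expression matrix must have transcript and sample names")
  else {
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, sprintf("duplicate transcript ID: %s",
                            rownames(m)[duplicated(rownames(m))][1L]))
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, sprintf("duplicate sample ID: %s",
                            colnames(m)[duplicated(colnames(m))][1L]))
  }
  if (!all(is.finite(m)))
    msg <- c(msg, "expression values must all be finite")
  if (nrow(m) < 2L) msg <- c(msg, "at least 2 transcripts required")
  if (ncol(m) < 3L) msg <- c(msg, "at least 3 samples required")
  cd <- SummarizedExperiment::colData(object)
  missing <- setdiff(.REQUIRED_META, colnames(cd))
  if (length(missing))
    msg <- c(msg, paste0("metadata columns missing: ",
                         paste(missing, collapse = ", ")))
  else {
    if (any(!is.finite(cd$age)) || any(cd$age <= 0))
      msg <- c(msg, "age must be finite and strictly positive")
    if (any(!cd$sex %in% c("female", "male")))
      msg <- c(msg, "sex must be 'female' or 'male'")
    if (any(!is.finite(cd$rin)) || any(cd$rin < 0 | cd$rin > 10))
      msg <- c(msg, "rin must lie in [0, 10]")
    if (any(!is.finite(cd$pmi)) || any(cd$pmi < 0))
      msg <- c(msg, "pmi must be non-negative")
    if (any(!is.finite(cd$intronic_mean)))
      msg <- c(msg, "intronic_mean must be finite")
    if (any(!is.finite(cd$intronic_sd)) || any(cd$intronic_sd < 0))
      msg <- c(msg, "intronic_sd must be finite and non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AgingCohort
#'
#' @param expr numeric matrix, transcripts x samples, with unique row and
#'   column names; normalized log-scale expression.
#' @param metadata data.frame (or DataFrame) with one row per sample, in the
#'   same order as `colnames(expr)` or row-named by sample ID; must contain
#'   columns `age`, `sex`, `rin`, `pmi`, `batch`, `intronic_mean`,
#'   `intronic_sd`.
#' @param annotation optional two-column data.frame (`transcript_id`,
#'   `gene_symbol`) or a named character vector mapping transcript to gene;
#'   stored in `rowData(x)$gene_symbol`.
#'
#' @return An [AgingCohort-class] object.
#' @examples
#' sim <- simulateCohort(simulationConfig(seed = 1))
#' sim$cohort
#' @export
AgingCohort <- function(expr, metadata, annotation = NULL) {
  expr <- .checkExprMatrix(expr)
  metadata <- as.data.frame(metadata)
  if (!is.null(rownames(metadata)) &&
      all(colnames(expr) %in% rownames(metadata)))
    metadata <- metadata[colnames(expr), , drop = FALSE]
  if (nrow(metadata) != ncol(expr))
    stop("metadata must have one row per sample")
  rowdat <- S4Vectors::DataFrame(row.names = rownames(expr))
  if (!is.null(annotation)) {
    map <- .annotationMap(annotation)
    missing <- setdiff(rownames(expr), names(map))
    if (length(missing))
      stop("unannotated transcripts: ",
           paste(head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ...")
    rowdat$gene_symbol <- unname(map[rownames(expr)])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr),
    colData = S4Vectors::DataFrame(metadata, row.names = colnames(expr)),
    rowData = rowdat)
  new("AgingCohort", se)
}

# normalize an annotation argument to a named character vector
.annotationMap <- function(annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(ncol(annotation) >= 2L)
    map <- as.character(annotation[[2L]])
    names(map) <- as.character(annotation[[1L]])
  } else if (is.character(annotation) && !is.null(names(annotation))) {
    map <- annotation
  } else stop("annotation must be a data.frame or named character vector")
  if (anyDuplicated(names(map)))
    stop("transcript annotated more than once: ",
         names(map)[duplicated(names(map))][1L])
  map
}

#' @describeIn AgingCohort Expression matrix accessor.
#' @param x an `AgingCohort`
#' @export
exprValues <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "expr")
  else .checkExprMatrix(x)
}

#' @describeIn AgingCohort Donor ages (years), named by sample.
#' @export
sampleAges <- function(x) {
  a <- SummarizedExperiment::colData(x)$age
  names(a) <- colnames(x)
  a
}

#' @describeIn AgingCohort Transcript-to-gene map from `rowData`, or NULL.
#' @export
geneSymbols <- function(x) {
  g <- SummarizedExperiment::rowData(x)$gene_symbol
  if (is.null(g)) return(NULL)
  names(g) <- rownames(x)
  g
}

setMethod("show", "AgingCohort", function(object) {
  cat("AgingCohort:", nrow(object), "transcripts x", ncol(object),
      "samples\n")
  ages <- SummarizedExperiment::colData(object)$age
  cat(sprintf("  age range %.1f-%.1f years; %d female / %d male\n",
              min(ages), max(ages),
              sum(SummarizedExperiment::colData(object)$sex == "female"),
              sum(SummarizedExperiment::colData(object)$sex == "male")))
  g <- geneSymbols(object)
  if (!is.null(g))
    cat("  annotated to", length(unique(g)), "genes\n")
  invisible(NULL)
})

#' Signed weighted co-expression network
#'
#' Container for the product of [buildNetwork()]: the signed adjacency,
#' the topological overlap matrix (TOM), color-style module labels (with
#' `"grey"` for unassigned transcripts), module eigengenes, per-module
#' variance explained, per-transcript total and within-module connectivity,
#' and the hub transcript of each module.
#'
#' @slot adjacency symmetric matrix in \[0,1\], unit diagonal.
#' @slot tom symmetric TOM in \[0,1\], unit diagonal.
#' @slot moduleLabels named character vector per transcript.
#' @slot eigengenes modules x samples matrix; each row unit Euclidean norm.
#' @slot varianceExplained named numeric per module, in \[0,1\].
#' @slot kTotal,kWithin named numeric connectivities per transcript.
#' @slot hubs named character: per-module transcript maximizing kWithin.
#' @slot params list of the construction parameters.
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
         representation(adjacency = "matrix", tom = "matrix",
                        moduleLabels = "character", eigengenes = "matrix",
                        varianceExplained = "numeric", kTotal = "numeric",
                        kWithin = "numeric", hubs = "character",
                        params = "list"))

#' Accessors for CoexpressionNetwork results
#'
#' `moduleLabels()` returns the per-transcript module labels,
#' `eigengenes()` the modules-by-samples eigengene matrix, and
#' `moduleHubs()` the hub transcript of each non-grey module.
#'
#' @param x a [CoexpressionNetwork-class]
#' @return see description.
#' @name network-accessors
#' @export
moduleLabels <- function(x) x@moduleLabels

#' @rdname network-accessors
#' @export
eigengenes <- function(x) x@eigengenes

#' @rdname network-accessors
#' @export
moduleHubs <- function(x) x@hubs

setMethod("show", "CoexpressionNetwork", function(object) {
  lab <- object@moduleLabels
  nm <- sum(unique(lab) != "grey")
  cat("CoexpressionNetwork:", length(lab), "transcripts,",
      nm, "modules (+grey)\n")
  cat("  soft power", object@params$power,
      "| min module size", object@params$minModuleSize,
      "| cut height", object@params$cutHeight, "\n")
  tab <- sort(table(lab[lab != "grey"]), decreasing = TRUE)
  if (length(tab))
    cat("  sizes:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = " "), "\n")
  cat("  grey:", sum(lab == "grey"), "\n")
  invisible(NULL)
})

#' Scale-free topology fit across candidate soft powers
#'
#' @slot table data.frame with columns `power`, `fit` (signed R^2 of the
#'   log10 p(k) on log10 k regression), `meanK`, `medianK`, `maxK`.
#' @slot chosenPower the selected soft-thresholding power.
#' @slot targetFit the fit threshold used for selection.
#' @exportClass ScaleFreeFit
setClass("ScaleFreeFit",
         representation(table = "data.frame", chosenPower = "numeric",
                        targetFit = "numeric"))

#' Chosen soft power of a ScaleFreeFit
#' @param x a [ScaleFreeFit-class]
#' @return the selected soft-thresholding power (numeric scalar).
#' @export
chosenPower <- function(x) x@chosenPower

setMethod("show", "ScaleFreeFit", function(object) {
  cat("ScaleFreeFit: chosen power", object@chosenPower,
      sprintf("(target fit %.2f)\n", object@targetFit))
  print(object@table, row.names = FALSE, digits = 3)
  invisible(NULL)
})

#' Collection of named gene sets (GMT-style)
#'
#' @slot setIds unique set identifiers.
#' @slot setNames human-readable set names (descriptions).
#' @slot members list of character vectors of gene symbols, one per set.
#' @seealso [readGMT()], [enrichModule()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(setIds = "character", setNames = "character",
                        members = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (anyDuplicated(object@setIds))
    msg <- c(msg, "set ids must be unique")
  if (length(object@setIds) != length(object@members) ||
      length(object@setIds) != length(object@setNames))
    msg <- c(msg, "ids, names and members must be parallel")
  if (any(!vapply(object@members, length, 1L)))
    msg <- c(msg, "every set must have at least one member")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#' @param members named list of character vectors (names become set ids).
#' @param setNames optional descriptions, defaults to the ids.
#' @return a [GeneSetCollection-class]
#' @export
GeneSetCollection <- function(members, setNames = NULL) {
  ids <- names(members)
  if (is.null(ids)) stop("members must be a named list")
  if (is.null(setNames)) setNames <- ids
  new("GeneSetCollection", setIds = ids, setNames = as.character(setNames),
      members = lapply(members, as.character))
}

#' @describeIn GeneSetCollection set ids
#' @param object,x a `GeneSetCollection`
#' @export
geneSetIds <- function(x) x@setIds

#' @describeIn GeneSetCollection member lists, named by set id
#' @export
geneSetMembers <- function(x) {
  m <- x@members
  names(m) <- x@setIds
  m
}

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@setIds), "sets;",
      "median size", stats::median(vapply(object@members, length, 1L)), "\n")
  invisible(NULL)
})

setMethod("length", "GeneSetCollection", function(x) length(x@setIds))

# shared expression-matrix checks used by matrix-level entry points
.checkExprMatrix <- function(m, min_samples = 1L) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression must be a numeric matrix (transcripts x samples)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have row (transcript) and column (sample) names")
  if (anyDuplicated(rownames(m)))
    stop("duplicate transcript ID: ", rownames(m)[duplicated(rownames(m))][1L])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ID: ", colnames(m)[duplicated(colnames(m))][1L])
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at row '%s', column '%s'",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
  }
  if (ncol(m) < min_samples)
    stop("at least ", min_samples, " samples required")
  m
}
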