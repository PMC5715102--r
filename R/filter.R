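#' Filter transcripts against intronic background
#'
#' A transcript counts as detected in a sample when its expression exceeds
#' that sample's intronic background mean by strictly more than one intronic
#' SD. A transcript is retained when it is detected in strictly more than
#' `detectionFraction` of samples (default 0.95). `detectionFraction = 1`
#' is special-cased to mean "detected in all samples", since a strict
#' inequality against n would be unsatisfiable.
#'
#' With `perSample = FALSE` a single global threshold is used instead:
#' the cross-sample mean of `intronic_mean` plus the cross-sample mean of
#' `intronic_sd`.
#'
#' The operation is idempotent: filtering an already-filtered matrix
#' changes nothing. Retained transcripts keep their input order.
#'
#' @param x an [AgingCohort-class], or a numeric expression matrix
#'   (transcripts x samples).
#' @param intronicMean,intronicSD per-sample background summaries (numeric,
#'   one per sample); taken from `colData` when `x` is an `AgingCohort`.
#' @param detectionFraction required detected fraction, in (0, 1].
#' @param perSample logical; per-sample thresholds (default) or one pooled
#'   global threshold.
#' @return object of the same class as `x`, restricted to retained
#'   transcripts.
#' @examples
#' sim <- simulateCohort(simulationConfig(seed = 1))
#' filterDetected(sim$cohort)
#' @export
setGeneric("filterDetected", function(x, ...) standardGeneric("filterDetected"))

#' @rdname filterDetected
#' @param ... passed through to the matrix method.
#' @export
setMethod("filterDetected", "matrix",
  function(x, intronicMean, intronicSD, detectionFraction = 0.95,
           perSample = TRUE) {
    m <- .checkExprMatrix(x, min_samples = 1L)
    n <- ncol(m)
    if (length(intronicMean) != n || length(intronicSD) != n)
      stop("intronicMean/intronicSD must have one value per sample")
    if (any(!is.finite(intronicMean)) || any(!is.finite(intronicSD)))
      stop("intronic background summaries must be finite")
    if (any(intronicSD < 0)) stop("intronic_sd must be non-negative")
    if (!is.numeric(detectionFraction) || length(detectionFraction) != 1L ||
        detectionFraction <= 0 || detectionFraction > 1)
      stop("detectionFraction must lie in (0, 1]")
    if (perSample) {
      thr <- intronicMean + intronicSD
    } else {
      thr <- rep(mean(intronicMean) + mean(intronicSD), n)
    }
    detected <- sweep(m, 2L, thr, ">")
    counts <- rowSums(detected)
    keep <- if (detectionFraction == 1) counts >= n
            else counts > detectionFraction * n
    m[keep, , drop = FALSE]
  })

#' @rdname filterDetected
#' @export
setMethod("filterDetected", "AgingCohort",
  function(x, detectionFraction = 0.95, perSample = TRUE) {
    cd <- SummarizedExperiment::colData(x)
    kept <- filterDetected(exprValues(x),
                           intronicMean = cd$intronic_mean,
                           intronicSD = cd$intronic_sd,
                           detectionFraction = detectionFraction,
                           perSample = perSample)
    x[rownames(kept), ]
  })

#' Collapse transcripts to one representative per gene
#'
#' For each gene the transcript with the highest mean expression across
#' samples is chosen; ties are broken by the lexicographically smallest
#' transcript ID. This mirrors the convention used when comparing
#' transcript-level results with gene-level external datasets.
#'
#' @param x an [AgingCohort-class] with gene annotation in `rowData`, or a
#'   numeric expression matrix.
#' @param annotation named character vector (transcript -> gene); required
#'   for the matrix method, ignored (taken from `rowData`) for cohorts.
#' @return For a matrix: a list with `values` (gene-level matrix, rows named
#'   by gene) and `map` (data.frame `gene`, `transcript`). For a cohort: a
#'   gene-level `AgingCohort` whose `rowData$transcript_id` records the
#'   chosen transcript.
#' @export
setGeneric("collapseToGene", function(x, ...) standardGeneric("collapseToGene"))

#' @rdname collapseToGene
#' @param ... passed through to the matrix method.
#' @export
setMethod("collapseToGene", "matrix", function(x, annotation) {
  m <- .checkExprMatrix(x, min_samples = 1L)
  map <- .annotationMap(annotation)
  missing <- setdiff(rownames(m), names(map))
  if (length(missing))
    stop("unannotated transcripts: ",
         paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  genes <- unname(map[rownames(m)])
  means <- rowMeans(m)
  # order: gene, then decreasing mean, then transcript ID; first row per gene wins
  ord <- order(genes, -means, rownames(m), method = "radix")
  first <- ord[!duplicated(genes[ord])]
  chosen <- rownames(m)[first]
  out <- m[chosen, , drop = FALSE]
  rownames(out) <- genes[first]
  list(values = out,
       map = data.frame(gene = genes[first], transcript = chosen,
                        stringsAsFactors = FALSE))
})

#' @rdname collapseToGene
#' @export
setMethod("collapseToGene", "AgingCohort", function(x) {
  g <- geneSymbols(x)
  if (is.null(g))
    stop("cohort has no gene annotation in rowData(x)$gene_symbol")
  res <- collapseToGene(exprValues(x), annotation = g)
  cohort <- AgingCohort(res$values,
                        as.data.frame(SummarizedExperiment::colData(x)))
  SummarizedExperiment::rowData(cohort)$gene_symbol <- res$map$gene
  SummarizedExperiment::rowData(cohort)$transcript_id <- res$map$transcript
  cohort
})
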