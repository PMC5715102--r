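## Cross-dataset validation of age-association profiles: transcript-to-gene
## collapse with divergence exclusion, correlation of per-gene R vectors
## between datasets, and region-panel summaries.

#' Collapse transcript associations to genes, excluding divergent genes
#'
#' A gene is divergent — and excluded — when at least two of its
#' transcripts are each nominally significant (p below `threshold`) with
#' opposite signs of R. Every surviving gene is represented by its
#' transcript with the highest mean expression (ties broken by the
#' lexicographically smallest transcript ID). Single-transcript genes are
#' never excluded.
#'
#' @param associations transcript-level table from
#'   [transcriptAgeAssociations()].
#' @param annotation named character vector (transcript -> gene) or
#'   two-column data.frame.
#' @param threshold nominal significance threshold defining divergence.
#' @return data.frame (one row per surviving gene): `gene`, `transcript`,
#'   `R`, `p_nominal`, `mean_expr`; attribute `divergent_genes` lists the
#'   excluded genes.
#' @export
collapseWithDivergenceFilter <- function(associations, annotation,
                                         threshold = 0.05) {
  map <- .annotationMap(annotation)
  missing <- setdiff(associations$transcript_id, names(map))
  if (length(missing))
    stop("unannotated transcripts: ",
         paste(head(missing, 5L), collapse = ", "))
  gene <- unname(map[associations$transcript_id])
  sig <- associations$p_nominal < threshold
  pos <- tapply(sig & associations$R > 0, gene, any)
  neg <- tapply(sig & associations$R < 0, gene, any)
  divergent <- names(pos)[pos & neg]
  keep <- !(gene %in% divergent)
  a <- associations[keep, ]; g <- gene[keep]
  ord <- order(g, -a$mean_expr, a$transcript_id, method = "radix")
  first <- ord[!duplicated(g[ord])]
  out <- data.frame(gene = g[first],
                    transcript = a$transcript_id[first],
                    R = a$R[first], p_nominal = a$p_nominal[first],
                    mean_expr = a$mean_expr[first],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  attr(out, "divergent_genes") <- sort(divergent)
  out
}

#' Compare per-gene age associations between two datasets
#'
#' Restricts both tables to their gene intersection and correlates the two
#' R vectors (Pearson), with a nominal two-sided p. The per-gene merged
#' table is returned for scatter export, with a point-size column of
#' `-log10` of the smaller nominal p.
#'
#' @param a,b gene-level tables with columns `gene`, `R` and optionally
#'   `p_nominal` (e.g. from [collapseWithDivergenceFilter()] or a collapsed
#'   [transcriptAgeAssociations()] renamed to genes).
#' @return list: `R`, `p`, `n_genes`, `table` (gene, R_a, R_b, size).
#' @export
compareAgeAssociations <- function(a, b) {
  shared <- intersect(a$gene, b$gene)
  if (length(shared) < 10L)
    stop("fewer than 10 shared genes between the datasets")
  ia <- match(shared, a$gene); ib <- match(shared, b$gene)
  r <- cor(a$R[ia], b$R[ib])
  pa <- if ("p_nominal" %in% colnames(a)) a$p_nominal[ia] else NA_real_
  pb <- if ("p_nominal" %in% colnames(b)) b$p_nominal[ib] else NA_real_
  size <- -log10(pmax(pmin(pa, pb, na.rm = TRUE), 1e-300))
  list(R = r, p = .corPvalue(r, length(shared)), n_genes = length(shared),
       table = data.frame(gene = shared, R_a = a$R[ia], R_b = b$R[ib],
                          size = size, stringsAsFactors = FALSE))
}

#' Pairwise age-association agreement across a panel of datasets
#'
#' For every dataset pair, [compareAgeAssociations()] over the pairwise
#' gene intersection; diagonal defined as 1. Per-dataset significant
#' counts (nominal p < `threshold`, split by sign of R) are reported as in
#' region-panel summaries.
#'
#' @param tables named list of gene-level association tables (>= 2), each
#'   with columns `gene`, `R`, `p_nominal`.
#' @param threshold nominal p threshold for the counts.
#' @return list: `R_matrix` (symmetric, unit diagonal) and `counts`
#'   (data.frame: dataset, positive, negative).
#' @export
regionPanel <- function(tables, threshold = 0.05) {
  if (length(tables) < 2L) stop("need at least 2 datasets")
  if (is.null(names(tables)))
    names(tables) <- sprintf("dataset%d", seq_along(tables))
  k <- length(tables)
  rmat <- diag(1, k)
  dimnames(rmat) <- list(names(tables), names(tables))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    r <- compareAgeAssociations(tables[[i]], tables[[j]])$R
    rmat[i, j] <- r; rmat[j, i] <- r
  }
  counts <- do.call(rbind, lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    cs <- countSignificant(
      data.frame(R = tab$R, p_nominal = tab$p_nominal),
      threshold = threshold, mode = "nominal")
    data.frame(dataset = nm, positive = cs[["positive"]],
               negative = cs[["negative"]], stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(R_matrix = rmat, counts = counts)
}
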