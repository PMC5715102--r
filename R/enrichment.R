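## Hypergeometric over-representation of gene sets in modules, with
## Benjamini-Hochberg correction within each module.

#' Gene-set over-representation for one module
#'
#' Upper-tail hypergeometric test per set: with a universe of `N` genes of
#' which `K` belong to the set and a module of `n` genes overlapping the
#' set in `k`, `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`. P values are
#' Benjamini-Hochberg adjusted across the sets tested for the module and
#' results are sorted by ascending p; the best term carries `top = TRUE`.
#' Gene symbols are uppercased for matching. Sets with no universe overlap
#' are skipped (their count is recorded in the `n_skipped` attribute).
#'
#' @param moduleGenes gene symbols of the module.
#' @param collection a [GeneSetCollection-class].
#' @param universe background gene symbols; must contain the module genes.
#' @return data.frame: `set_id`, `set_name`, `overlap` (k), `module_size`
#'   (n), `set_size` (K), `universe_size` (N), `p_nominal`, `p_adjusted`,
#'   `top`; attribute `n_skipped`.
#' @examples
#' sets <- GeneSetCollection(list(S1 = c("A", "B", "C"), S2 = c("D", "E")))
#' enrichModule(c("A", "B", "X"), sets, universe = c(LETTERS, "AA"))
#' @export
enrichModule <- function(moduleGenes, collection, universe) {
  stopifnot(is(collection, "GeneSetCollection"))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("universe is empty")
  moduleGenes <- unique(toupper(moduleGenes))
  outside <- setdiff(moduleGenes, universe)
  if (length(outside))
    stop("module genes outside the universe: ",
         paste(head(outside, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(moduleGenes)
  rows <- list()
  skipped <- 0L
  members <- geneSetMembers(collection)
  for (i in seq_along(members)) {
    set <- intersect(toupper(members[[i]]), universe)
    K <- length(set)
    if (!K) { skipped <- skipped + 1L; next }
    k <- length(intersect(set, moduleGenes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = collection@setIds[i], set_name = collection@setNames[i],
      overlap = k, module_size = n, set_size = K, universe_size = N,
      p_nominal = p, stringsAsFactors = FALSE)
  }
  if (skipped)
    message(skipped, " set(s) with no universe overlap skipped")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_id = character(0), set_name = character(0),
               overlap = integer(0), module_size = integer(0),
               set_size = integer(0), universe_size = integer(0),
               p_nominal = numeric(0))
  if (nrow(out)) {
    out$p_adjusted <- p.adjust(out$p_nominal, method = "BH")
    out <- out[order(out$p_nominal, out$set_id), ]
    out$top <- seq_len(nrow(out)) == 1L
  } else {
    out$p_adjusted <- numeric(0); out$top <- logical(0)
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Enrichment across all modules of a network
#'
#' Runs [enrichModule()] for every non-grey module. The default universe
#' is all annotated genes in the network (the detection-filtered
#' background).
#'
#' @param network a [CoexpressionNetwork-class].
#' @param annotation transcript -> gene map for the network's transcripts.
#' @param collection a [GeneSetCollection-class].
#' @param universe background genes; defaults to all genes in `annotation`
#'   restricted to the network's transcripts.
#' @return data.frame of [enrichModule()] rows with a leading `module`
#'   column; per module the best term carries `top = TRUE`.
#' @export
enrichAllModules <- function(network, annotation, collection,
                             universe = NULL) {
  map <- .annotationMap(annotation)
  labels <- network@moduleLabels
  genes_by_tx <- unname(map[names(labels)])
  if (is.null(universe)) universe <- unique(genes_by_tx)
  mods <- setdiff(unique(labels), "grey")
  res <- lapply(mods, function(mod) {
    mg <- unique(genes_by_tx[labels == mod])
    tab <- enrichModule(mg, collection, universe)
    if (nrow(tab)) cbind(module = mod, tab, stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
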