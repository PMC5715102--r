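## Signed weighted co-expression network construction.
## Adjacency a_ij = ((1 + cor_ij)/2)^beta; TOM per the standard weighted
## topological overlap; static average-linkage tree cut with min-size merge
## into "grey"; eigengenes as first right singular vectors of standardized
## module expression.

# WGCNA color convention, by decreasing module size
.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue",
                    "darkred", "darkgreen", "darkturquoise", "darkgrey",
                    "orange", "darkorange", "white")

.moduleColorNames <- function(k) {
  if (k <= length(.MODULE_COLORS)) .MODULE_COLORS[seq_len(k)]
  else c(.MODULE_COLORS, sprintf("module%d", seq_len(k - length(.MODULE_COLORS))))
}

#' Signed co-expression adjacency
#'
#' `A_ij = ((1 + cor(x_i, x_j)) / 2)^beta` with Pearson correlation across
#' samples, so anti-correlated transcripts receive near-zero adjacency.
#' The diagonal is set to 1.
#'
#' @param expr numeric matrix (transcripts x samples) or
#'   [AgingCohort-class]; at least 3 samples; no zero-variance rows.
#' @param power soft-thresholding exponent beta (positive; the cohort-scale
#'   default in this pipeline is 6).
#' @return symmetric adjacency matrix in \[0,1\].
#' @examples
#' x <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("t", 1:4), paste0("s", 1:10)))
#' a <- signedAdjacency(x, power = 6)
#' @export
signedAdjacency <- function(expr, power = 6) {
  m <- exprValues(expr)
  .checkExprMatrix(m, min_samples = 3L)
  if (!is.numeric(power) || length(power) != 1L || power < 1)
    stop("power must be a positive scalar >= 1")
  v <- apply(m, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance transcript: ", rownames(m)[which(v == 0)[1L]])
  cc <- cor(t(m))
  a <- ((1 + cc) / 2)^power
  a <- (a + t(a)) / 2              # enforce exact symmetry
  a[a > 1] <- 1; a[a < 0] <- 0
  diag(a) <- 1
  a
}

# scale-free fit statistic of a connectivity vector:
# equal-width binning of k, regression of log10 p(k) on log10 mean(k);
# fit = -sign(slope) * R^2 (high when the degree distribution decays)
.scaleFreeFitIndex <- function(k, nBins = 10L) {
  if (max(k) - min(k) < 1e-12) {
    warning("all connectivities identical; scale-free fit undefined, returning 0")
    return(0)
  }
  bins <- cut(k, breaks = nBins, include.lowest = TRUE)
  mk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  keep <- !is.na(mk) & mk > 0 & !is.na(pk) & pk > 0
  if (sum(keep) < 3L) {
    warning("too few populated connectivity bins; scale-free fit set to 0")
    return(0)
  }
  fit <- stats::lm(log10(pk[keep]) ~ log10(mk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2L]
  if (!is.finite(r2) || !is.finite(slope)) return(0)
  -sign(slope) * r2
}

#' Choose a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the signed adjacency is formed, connectivity
#' `k_i = sum_j A_ij - 1` computed, and the scale-free fit evaluated as the
#' signed R^2 of the `log10 p(k)` on `log10 k` regression over ten
#' connectivity bins. The chosen power is the smallest candidate whose fit
#' reaches `targetFit`; if none does, the best-fitting power is returned
#' with a warning.
#'
#' @param expr matrix or [AgingCohort-class].
#' @param powers candidate powers.
#' @param targetFit required fit (default 0.8).
#' @param nBins number of connectivity bins.
#' @return a [ScaleFreeFit-class].
#' @export
pickSoftThreshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                              targetFit = 0.8, nBins = 10L) {
  m <- exprValues(expr)
  .checkExprMatrix(m, min_samples = 3L)
  if (!length(powers)) stop("candidate powers must be non-empty")
  powers <- sort(unique(as.numeric(powers)))
  cc <- cor(t(m))
  s <- (1 + cc) / 2
  diag(s) <- 0                      # exclude self from connectivity
  rows <- lapply(powers, function(b) {
    a <- s^b
    k <- colSums(a)
    data.frame(power = b, fit = .scaleFreeFitIndex(k, nBins = nBins),
               meanK = mean(k), medianK = stats::median(k), maxK = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$fit >= targetFit)
  if (length(ok)) {
    chosen <- tab$power[ok[1L]]
  } else {
    chosen <- tab$power[which.max(tab$fit)]
    warning(sprintf(
      "no candidate power reached fit %.2f; using power %g (fit %.3f)",
      targetFit, chosen, max(tab$fit)))
  }
  new("ScaleFreeFit", table = tab, chosenPower = chosen,
      targetFit = targetFit)
}

#' Topological overlap matrix
#'
#' For `i != j`:
#' `TOM_ij = (sum_u A_iu A_uj (u != i,j) + A_ij) / (min(k_i, k_j) + 1 - A_ij)`
#' with `k_i = sum_{u != i} A_iu`; the diagonal is 1. The clustering
#' dissimilarity used downstream is `1 - TOM`.
#'
#' @param adjacency symmetric matrix with unit diagonal, values in \[0,1\].
#' @return symmetric TOM in \[0,1\] with unit diagonal.
#' @export
topologicalOverlap <- function(adjacency) {
  a <- adjacency
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix")
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    stop("adjacency values must lie in [0, 1]")
  if (max(abs(diag(a) - 1)) > 1e-12)
    stop("adjacency diagonal must be 1")
  k <- colSums(a) - 1
  aa <- a %*% a
  # shared-neighbor sum excluding u in {i, j}: (A^2)_ij - 2 A_ij given diag 1;
  # numerator adds the direct edge back once
  num <- aa - a
  den <- outer(k, k, pmin) + 1 - a
  diag(den) <- 1                      # diagonal is overwritten below
  if (any(den <= 0))
    stop("non-positive TOM denominator; adjacency is not a valid signed network")
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  tom[tom < 0] <- 0; tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by static tree cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at `cutHeight`; clusters smaller than `minModuleSize` are merged into
#' `"grey"`. Surviving modules are named by decreasing size following the
#' WGCNA color convention (turquoise, blue, brown, ...). Deterministic
#' given its input.
#'
#' Note that average-linkage merge heights on `1 - TOM` are bounded above
#' by 1, so a literal cut at the cohort-scale default `cutHeight = 1`
#' yields a single cluster; desk-scale analyses in this package cut at
#' 0.95 (see the methods vignette).
#'
#' @param dissimilarity symmetric matrix, typically `1 - topologicalOverlap(A)`.
#' @param minModuleSize smallest cluster kept as a module (cohort-scale
#'   default 200; tests use 10).
#' @param cutHeight static cut height on the dendrogram.
#' @return named character vector of module labels (including `"grey"`).
#' @export
detectModules <- function(dissimilarity, minModuleSize = 200, cutHeight = 1) {
  d <- dissimilarity
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("dissimilarity must be a square matrix")
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- sprintf("node%d", seq_len(n))
  if (minModuleSize > n) {
    warning("minModuleSize exceeds the number of transcripts; all grey")
    return(stats::setNames(rep("grey", n), ids))
  }
  tree <- hclust(as.dist(d), method = "average")
  cl <- cutree(tree, h = cutHeight)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  labels <- rep("grey", n)
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    colors <- .moduleColorNames(length(keep))
    for (i in seq_along(keep))
      labels[cl == as.integer(keep[i])] <- colors[i]
  }
  stats::setNames(labels, ids)
}

#' Module eigengenes
#'
#' Each member transcript is standardized across samples; the module
#' eigengene is the first right singular vector of the standardized
#' members-by-samples matrix (unit Euclidean norm), with its sign oriented
#' so it correlates non-negatively with the module's mean standardized
#' expression. `varianceExplained` is the leading squared singular value
#' over the total.
#'
#' @param expr matrix or [AgingCohort-class].
#' @param labels module labels aligned to `rownames(expr)`; `"grey"` is
#'   skipped.
#' @return list with `eigengenes` (modules x samples matrix, rows unit norm)
#'   and `varianceExplained` (named numeric in \[0,1\]).
#' @export
moduleEigengenes <- function(expr, labels) {
  m <- exprValues(expr)
  .checkExprMatrix(m, min_samples = 3L)
  labels <- .alignLabels(labels, rownames(m))
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey module in labels")
  mods <- mods[order(match(mods, .MODULE_COLORS), mods)]
  me <- matrix(NA_real_, length(mods), ncol(m),
               dimnames = list(mods, colnames(m)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (mod in mods) {
    x <- m[labels == mod, , drop = FALSE]
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance transcript in module ", mod, ": ",
           rownames(x)[which(sds == 0)[1L]])
    xs <- (x - rowMeans(x)) / sds
    if (nrow(xs) == 1L) {
      v <- xs[1L, ] / sqrt(sum(xs[1L, ]^2))
      me[mod, ] <- v
      ve[mod] <- 1
      next
    }
    sv <- svd(xs, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    if (cor(v, colMeans(xs)) < 0) v <- -v
    me[mod, ] <- v
    ve[mod] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, varianceExplained = ve)
}

.alignLabels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing))
      stop("labels missing for transcripts: ",
           paste(head(missing, 5L), collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels must be named or aligned to the expression rows")
  }
  stats::setNames(as.character(labels), ids)
}

#' Connectivity and module hubs
#'
#' `kTotal_i` is transcript i's summed adjacency to all other transcripts;
#' `kWithin_i` restricts the sum to transcripts sharing i's module label.
#' The hub of each non-grey module is its `kWithin` maximizer, ties broken
#' by the lexicographically smallest transcript ID; grey has no hub.
#'
#' @param adjacency signed adjacency matrix.
#' @param labels module labels aligned to the adjacency rows.
#' @return list with `kTotal`, `kWithin` (named numerics) and `hubs`
#'   (named character, one per non-grey module).
#' @export
connectivityAndHubs <- function(adjacency, labels) {
  a <- adjacency
  ids <- rownames(a)
  if (is.null(ids)) stop("adjacency must have row names")
  labels <- .alignLabels(labels, ids)
  k_total <- colSums(a) - 1
  k_within <- stats::setNames(numeric(length(ids)), ids)
  for (mod in unique(labels)) {
    idx <- which(labels == mod)
    k_within[idx] <- colSums(a[idx, idx, drop = FALSE]) - 1
  }
  mods <- setdiff(unique(labels), "grey")
  hubs <- stats::setNames(character(length(mods)), mods)
  for (mod in mods) {
    members <- ids[labels == mod]
    kw <- k_within[members]
    best <- members[kw == max(kw)]
    hubs[mod] <- sort(best)[1L]
  }
  names(k_total) <- ids
  list(kTotal = k_total, kWithin = k_within, hubs = hubs)
}

#' Build a signed co-expression network end to end
#'
#' Runs [signedAdjacency()], [topologicalOverlap()], [detectModules()],
#' [moduleEigengenes()] and [connectivityAndHubs()] and packages the result.
#'
#' @param expr matrix or [AgingCohort-class] (filtered expression).
#' @param power soft-thresholding power (default 6, the cohort-scale choice).
#' @param minModuleSize,cutHeight module detection parameters; see
#'   [detectModules()].
#' @return a [CoexpressionNetwork-class].
#' @examples
#' sim <- simulateCohort(simulationConfig(nModules = 2, genesPerModule = 15,
#'                                        nNoiseGenes = 20,
#'                                        markersPerCellType = 2,
#'                                        moduleAgeEffects = c(0.7, 0),
#'                                        moduleCellType = c(NA, NA),
#'                                        seed = 5))
#' net <- buildNetwork(filterDetected(sim$cohort), power = 6,
#'                     minModuleSize = 10, cutHeight = 0.95)
#' net
#' @export
buildNetwork <- function(expr, power = 6, minModuleSize = 200,
                         cutHeight = 1) {
  m <- exprValues(expr)
  a <- signedAdjacency(m, power = power)
  tom <- topologicalOverlap(a)
  labels <- detectModules(1 - tom, minModuleSize = minModuleSize,
                          cutHeight = cutHeight)
  if (all(labels == "grey")) {
    me <- matrix(numeric(0), 0L, ncol(m),
                 dimnames = list(NULL, colnames(m)))
    ve <- numeric(0)
    ch <- connectivityAndHubs(a, labels)
  } else {
    eg <- moduleEigengenes(m, labels)
    me <- eg$eigengenes; ve <- eg$varianceExplained
    ch <- connectivityAndHubs(a, labels)
  }
  new("CoexpressionNetwork", adjacency = a, tom = tom,
      moduleLabels = labels, eigengenes = me, varianceExplained = ve,
      kTotal = ch$kTotal, kWithin = ch$kWithin, hubs = ch$hubs,
      params = list(power = power, minModuleSize = minModuleSize,
                    cutHeight = cutHeight, networkType = "signed",
                    correlation = "pearson"))
}

#' Export the network as a weighted edge list
#'
#' Upper-triangle TOM edges at or above a weight threshold, suitable for
#' network viewers.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param threshold minimum TOM weight retained.
#' @param path optional TSV output path.
#' @return data.frame with `node1`, `node2`, `weight` (invisibly if written).
#' @export
exportEdgeList <- function(network, threshold = 0.1, path = NULL) {
  tom <- network@tom
  ids <- rownames(tom)
  ut <- upper.tri(tom)
  keep <- ut & tom >= threshold
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(node1 = ids[idx[, 1L]], node2 = ids[idx[, 2L]],
                   weight = tom[keep], stringsAsFactors = FALSE)
  df <- df[order(-df$weight, df$node1, df$node2), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Export module assignments with connectivity
#'
#' @param network a [CoexpressionNetwork-class].
#' @param annotation optional transcript -> gene map to add a gene column.
#' @return data.frame (transcript, gene, module, kTotal, kWithin).
#' @export
moduleAssignments <- function(network, annotation = NULL) {
  ids <- names(network@moduleLabels)
  df <- data.frame(transcript = ids,
                   gene = if (!is.null(annotation))
                     unname(.annotationMap(annotation)[ids]) else NA_character_,
                   module = unname(network@moduleLabels),
                   kTotal = unname(network@kTotal[ids]),
                   kWithin = unname(network@kWithin[ids]),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
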