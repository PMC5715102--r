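## Population-specific expression analysis (PSEA)-style deconvolution:
## per-sample cell-type reference signals built from marker genes,
## multiple regression of expression on the references, and residual
## correction of age associations for the neuronal signal.

#' Build per-sample cell-type reference signals from markers
#'
#' For each cell type, every present marker gene's expression vector is
#' divided by its own cross-sample mean (giving mean 1), and the scaled
#' markers are averaged across genes. The result is one relative abundance
#' signal per sample and cell type, each with cross-sample mean exactly 1.
#' Scaling each marker by its own mean makes the reference invariant to
#' multiplying any marker by a positive constant.
#'
#' Markers absent from the matrix are dropped with a warning; a cell type
#' with no present marker is an error. Marker means must be positive
#' (expression is assumed on a positive normalized scale).
#'
#' @param geneExpr gene-level matrix (genes x samples) or a collapsed
#'   [AgingCohort-class]; row names are gene symbols.
#' @param markers named list, cell type -> marker gene symbols (see
#'   [markerSets()]).
#' @return matrix, cell types x samples, each row mean 1.
#' @export
buildReferenceSignals <- function(geneExpr, markers) {
  m <- exprValues(geneExpr)
  .checkExprMatrix(m, min_samples = 2L)
  markers <- markerSets(markers)
  refs <- matrix(NA_real_, length(markers), ncol(m),
                 dimnames = list(names(markers), colnames(m)))
  for (ct in names(markers)) {
    present <- intersect(markers[[ct]], rownames(m))
    absent <- setdiff(markers[[ct]], rownames(m))
    if (!length(present))
      stop("no marker of cell type '", ct, "' present in the matrix")
    if (length(absent))
      warning(length(absent), " marker(s) of '", ct,
              "' absent from the matrix and dropped")
    sub <- m[present, , drop = FALSE]
    mu <- rowMeans(sub)
    if (any(mu <= 0))
      stop("marker '", present[which(mu <= 0)[1L]],
           "' has non-positive mean expression; references require a ",
           "positive scale")
    refs[ct, ] <- colMeans(sub / mu)
  }
  refs
}

#' Estimate per-gene cell-type contributions by multiple regression
#'
#' Ordinary least squares of each gene's expression on the cell-type
#' reference signals plus an intercept. Coefficients are relative
#' contribution estimates, not absolute fractions. Also reports the fit
#' R^2 and each gene's marginal Pearson correlation with every reference.
#'
#' @param geneExpr gene-level matrix or collapsed [AgingCohort-class].
#' @param references cell types x samples matrix from
#'   [buildReferenceSignals()].
#' @param maxCondition largest acceptable condition number of the design
#'   matrix; collinear references beyond it are a hard error.
#' @return list with `coefficients` (genes x (intercept + cell types)),
#'   `r_squared` (named numeric) and `marginal_cor` (genes x cell types).
#' @export
estimateCellContributions <- function(geneExpr, references,
                                      maxCondition = 1e8) {
  m <- exprValues(geneExpr)
  .checkExprMatrix(m, min_samples = 2L)
  if (ncol(references) != ncol(m))
    stop("references and expression must share samples")
  design <- cbind(intercept = 1, t(references))
  if (kappa(design, exact = TRUE) > maxCondition)
    stop("reference signals are collinear (condition number > ",
         format(maxCondition), "); revise the marker sets")
  if (ncol(m) <= ncol(design))
    stop("need more samples than regressors")
  qr_d <- qr(design)
  coefs <- t(qr.coef(qr_d, t(m)))
  fitted <- coefs %*% t(design)
  rss <- rowSums((m - fitted)^2)
  tss <- rowSums((m - rowMeans(m))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  names(r2) <- rownames(m)
  marg <- cor(t(m), t(references))
  list(coefficients = coefs, r_squared = r2, marginal_cor = marg)
}

#' Correct expression for the neuronal signal
#'
#' Residualizes every transcript (or gene) on the per-sample neuronal
#' reference signal (OLS with intercept) and adds the transcript's grand
#' mean back, so corrected values stay on the original scale and remain a
#' valid input for every downstream operation. Residuals have exactly zero
#' sample correlation with the reference.
#'
#' @param expr matrix or [AgingCohort-class].
#' @param neuronalReference per-sample signal (e.g. the `"neuron"` row of
#'   [buildReferenceSignals()]); must not be constant.
#' @return object of the same class as `expr` with corrected values.
#' @export
correctForNeurons <- function(expr, neuronalReference) {
  m <- exprValues(expr)
  .checkExprMatrix(m, min_samples = 3L)
  ref <- as.numeric(neuronalReference)
  if (length(ref) != ncol(m))
    stop("neuronalReference must have one value per sample")
  if (stats::sd(ref) == 0) stop("neuronal reference is constant")
  rc <- ref - mean(ref)
  mc <- m - rowMeans(m)
  beta <- (mc %*% rc) / sum(rc^2)
  corrected <- m - beta %*% t(rc)        # grand mean retained
  dimnames(corrected) <- dimnames(m)
  if (is(expr, "AgingCohort")) {
    out <- expr
    SummarizedExperiment::assay(out, "expr") <- corrected
    return(out)
  }
  corrected
}

#' Summarize age associations before and after neuronal correction
#'
#' Per module: mean R and mean `|R|` before and after, significant counts
#' at a nominal threshold, and the features significant in both. Features
#' named in `exclude` (for instance neuronal markers used to build the
#' reference, which would be circular) are flagged and left out of the
#' summaries.
#'
#' @param before,after association tables from
#'   [transcriptAgeAssociations()] on the uncorrected and corrected data;
#'   must cover the same feature universe.
#' @param labels module labels per feature (named, or aligned to `before`).
#' @param threshold nominal p threshold (default 0.05).
#' @param exclude feature IDs to flag out of the summaries.
#' @return list with `summary` (per-module data.frame: `module`, `n`,
#'   `mean_R_before`, `mean_R_after`, `mean_absR_before`, `mean_absR_after`,
#'   `n_sig_before`, `n_sig_after`) and `significant_in_both` (per-module
#'   list of feature IDs).
#' @export
compareCorrectedAssociations <- function(before, after, labels,
                                         threshold = 0.05,
                                         exclude = character(0)) {
  if (!setequal(before$transcript_id, after$transcript_id))
    stop("before/after tables cover different feature universes")
  after <- after[match(before$transcript_id, after$transcript_id), ]
  labels <- .alignLabels(labels, before$transcript_id)
  keep <- !(before$transcript_id %in% exclude)
  b <- before[keep, ]; a <- after[keep, ]; lab <- labels[keep]
  mods <- unique(lab)
  rows <- list(); both <- list()
  for (mod in mods) {
    i <- lab == mod
    sig_b <- b$p_nominal[i] < threshold
    sig_a <- a$p_nominal[i] < threshold
    rows[[mod]] <- data.frame(
      module = mod, n = sum(i),
      mean_R_before = mean(b$R[i]), mean_R_after = mean(a$R[i]),
      mean_absR_before = mean(abs(b$R[i])),
      mean_absR_after = mean(abs(a$R[i])),
      n_sig_before = sum(sig_b), n_sig_after = sum(sig_a),
      stringsAsFactors = FALSE)
    both[[mod]] <- b$transcript_id[i][sig_b & sig_a]
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, significant_in_both = both)
}
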