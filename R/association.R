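## Eigengene-covariate and transcript-age association tables.
## Pearson R, two-sided p from t = R * sqrt((n-2) / (1-R^2)) on n-2 df,
## Benjamini-Hochberg adjustment across the stated family.

# two-sided p for a Pearson correlation at n samples
.corPvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(abs(t), df, lower.tail = FALSE)
}

#' Correlate module eigengenes with cohort covariates
#'
#' Pearson correlation of each eigengene with each requested trait.
#' Numeric traits are used directly. Binary categorical traits (sex) are
#' encoded 0/1; a multi-level batch is expanded into per-level indicators
#' and the level with the largest `|R|` is reported for that trait.
#' Constant traits yield `R = 0`, `p = 1` and a `degenerate` flag with a
#' warning. P values are Benjamini-Hochberg adjusted across the full
#' module-by-trait grid.
#'
#' @param eigengenes modules x samples matrix (e.g. [eigengenes()] of a
#'   network).
#' @param metadata per-sample data.frame (or the [AgingCohort-class] whose
#'   `colData` is used), sample order matching the eigengene columns.
#' @param traits metadata columns to test.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame: `module`, `trait`, `level`, `R`, `p_nominal`,
#'   `p_adjusted`, `significant`, `degenerate`.
#' @export
eigengeneTraitAssociations <- function(eigengenes, metadata,
                                       traits = c("age", "sex", "rin",
                                                  "pmi", "batch"),
                                       alpha = 0.05) {
  if (is(metadata, "SummarizedExperiment"))
    metadata <- as.data.frame(SummarizedExperiment::colData(metadata))
  if (ncol(eigengenes) != nrow(metadata))
    stop("eigengene columns must match metadata rows")
  missing <- setdiff(traits, colnames(metadata))
  if (length(missing))
    stop("traits not in metadata: ", paste(missing, collapse = ", "))
  n <- ncol(eigengenes)
  rows <- list()
  for (mod in rownames(eigengenes)) {
    me <- eigengenes[mod, ]
    for (tr in traits) {
      v <- metadata[[tr]]
      if (is.numeric(v)) {
        enc <- list(.numeric = v)
      } else {
        lv <- sort(unique(as.character(v)))
        if (length(lv) < 2L) {
          enc <- stats::setNames(list(rep(0, n)), lv[1L])
        } else if (length(lv) == 2L) {
          enc <- stats::setNames(list(as.numeric(v == lv[2L])), lv[2L])
        } else {
          enc <- lapply(lv, function(l) as.numeric(v == l))
          names(enc) <- lv
        }
      }
      best <- NULL
      for (level in names(enc)) {
        x <- enc[[level]]
        degen <- stats::sd(x) == 0 || stats::sd(me) == 0
        r <- if (degen) 0 else cor(me, x)
        cand <- list(level = level, R = r, degenerate = degen)
        if (is.null(best) || abs(cand$R) > abs(best$R)) best <- cand
      }
      if (best$degenerate)
        warning("constant trait '", tr, "'; correlation reported as 0")
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, trait = tr,
        level = if (best$level == ".numeric") NA_character_ else best$level,
        R = best$R,
        p_nominal = if (best$degenerate) 1 else .corPvalue(best$R, n),
        degenerate = best$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_nominal, method = "BH")
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out[, c("module", "trait", "level", "R", "p_nominal", "p_adjusted",
          "significant", "degenerate")]
}

#' Per-transcript age associations with regression summaries
#'
#' Pearson correlation of each transcript with donor age, a two-sided
#' nominal p, Benjamini-Hochberg adjustment across transcripts, and the
#' least-squares line (slope, intercept) with the residual SD needed to
#' draw pointwise 95% confidence bands (see [confidenceBand()]).
#' Zero-variance transcripts are excluded with a warning.
#'
#' @param expr matrix or [AgingCohort-class] (>= 4 samples).
#' @param age donor ages; taken from `colData(x)$age` when `expr` is an
#'   `AgingCohort`.
#' @param alpha significance threshold on the adjusted p.
#' @return data.frame: `transcript_id`, `R`, `p_nominal`, `p_adjusted`,
#'   `significant`, `slope`, `intercept`, `sigma`, `n`, `mean_expr`;
#'   attributes `age_mean` and `age_ssx` carry the regressor summaries for
#'   confidence bands.
#' @export
transcriptAgeAssociations <- function(expr, age = NULL, alpha = 0.05) {
  m <- exprValues(expr)
  if (is.null(age)) {
    if (!is(expr, "SummarizedExperiment"))
      stop("age must be supplied for a matrix input")
    age <- SummarizedExperiment::colData(expr)$age
  }
  .checkExprMatrix(m, min_samples = 4L)
  if (length(age) != ncol(m)) stop("age must have one value per sample")
  n <- ncol(m)
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance transcripts: ",
            paste(head(rownames(m)[sds == 0], 5L), collapse = ", "),
            if (sum(sds == 0) > 5L) ", ...")
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!nrow(m)) stop("no transcript with non-zero variance")
  r <- as.vector(cor(t(m), age))
  slope <- r * sds / stats::sd(age)
  intercept <- rowMeans(m) - slope * mean(age)
  # residual SD of the least-squares fit on n-2 df
  sigma <- sds * sqrt(pmax(1 - r^2, 0) * (n - 1) / (n - 2))
  p <- .corPvalue(r, n)
  out <- data.frame(transcript_id = rownames(m), R = r, p_nominal = p,
                    p_adjusted = p.adjust(p, method = "BH"),
                    slope = slope, intercept = intercept, sigma = sigma,
                    n = n, mean_expr = rowMeans(m),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  attr(out, "age_mean") <- mean(age)
  attr(out, "age_ssx") <- sum((age - mean(age))^2)
  out
}

#' Pointwise confidence band of a transcript's age regression
#'
#' Reconstructs the fitted line and the pointwise confidence interval of
#' the mean response from the summaries stored by
#' [transcriptAgeAssociations()]:
#' half-width `t_{1-a/2, n-2} * sigma * sqrt(1/n + (x - xbar)^2 / ssx)`.
#'
#' @param associations table from [transcriptAgeAssociations()].
#' @param transcript transcript ID to plot.
#' @param ages ages at which to evaluate the band.
#' @param level confidence level (default 0.95).
#' @return data.frame: `age`, `fit`, `lower`, `upper`.
#' @export
confidenceBand <- function(associations, transcript, ages, level = 0.95) {
  i <- match(transcript, associations$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript)
  xbar <- attr(associations, "age_mean")
  ssx <- attr(associations, "age_ssx")
  if (is.null(xbar) || is.null(ssx))
    stop("associations table lacks the regression attributes")
  n <- associations$n[i]
  fit <- associations$intercept[i] + associations$slope[i] * ages
  half <- qt(1 - (1 - level) / 2, n - 2) * associations$sigma[i] *
    sqrt(1 / n + (ages - xbar)^2 / ssx)
  data.frame(age = ages, fit = fit, lower = fit - half, upper = fit + half)
}

#' Count significant associations by sign
#'
#' @param associations a table with columns `R` and `p_nominal` /
#'   `p_adjusted` (from [transcriptAgeAssociations()] or compatible).
#' @param threshold p threshold (default nominal 0.05).
#' @param mode `"nominal"` or `"adjusted"`.
#' @return named integer vector `c(positive =, negative =)`.
#' @export
countSignificant <- function(associations, threshold = 0.05,
                             mode = c("nominal", "adjusted")) {
  mode <- match.arg(mode)
  if (!nrow(associations)) stop("association table is empty")
  p <- switch(mode, nominal = associations$p_nominal,
              adjusted = associations$p_adjusted)
  sig <- !is.na(p) & p < threshold
  c(positive = sum(sig & associations$R > 0),
    negative = sum(sig & associations$R < 0))
}
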