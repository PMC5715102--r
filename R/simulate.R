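#' Configuration for the synthetic brain-aging cohort generator
#'
#' Describes a cohort in which co-expression modules, module-level age
#' effects, and age-drifting cell-type proportions are planted with known
#' ground truth. Defaults emulate a frontal-cortex RNA-Seq cohort of 60
#' donors aged 15-79 years with ten planted modules: six with direct age
#' effects of both signs, two cellularity-mediated modules (one tracking a
#' declining neuronal proportion, one tracking a rising oligodendrocyte
#' proportion, the pattern seen in aging cortex), and two null modules.
#'
#' @slot nSamples number of donors.
#' @slot ageRange (min, max) donor age in years; ages drawn uniformly.
#' @slot nModules number of planted co-expression modules.
#' @slot genesPerModule genes per planted module.
#' @slot nNoiseGenes unstructured noise genes.
#' @slot transcriptsPerGeneRange (min, max) transcripts per module/noise gene.
#' @slot moduleAgeEffects per-module target factor-age correlation in \[-1,1\].
#' @slot moduleCellType per-module cell-type label (or NA); the module factor
#'   then tracks that cell type's true proportion.
#' @slot withinModuleCor target pairwise correlation between transcripts of
#'   different genes in one module, in (0,1).
#' @slot cellAssocStrength correlation between a cellularity module's factor
#'   and its cell type's proportion.
#' @slot noiseSD expression noise scale (SD of a noise transcript, log units).
#' @slot transcriptNoiseSD SD of transcript-specific noise around the shared
#'   gene signal.
#' @slot cellTypes cell-type labels.
#' @slot baselineProportions mean proportion per cell type (sums to 1).
#' @slot proportionAgeSlopes per-cell-type proportion change per year.
#' @slot proportionNoiseSD per-cell-type SD of biological proportion noise.
#' @slot markersPerCellType marker genes planted per cell type.
#' @slot markerNoiseSD noise SD of marker genes around their proportion.
#' @slot intronicMean,intronicSD location of the intronic background noise
#'   floor (log units); per-sample summaries are drawn around these.
#' @slot belowDetectionFraction fraction of non-marker transcripts whose
#'   signal is replaced by background-level noise, to exercise the detection
#'   filter.
#' @slot baselineExpressionRange (min, max) of per-gene baseline expression.
#' @slot seed RNG seed; generation is bit-reproducible given the seed.
#' @seealso [simulationConfig()], [simulateCohort()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nSamples = "integer", ageRange = "numeric",
                        nModules = "integer", genesPerModule = "integer",
                        nNoiseGenes = "integer",
                        transcriptsPerGeneRange = "integer",
                        moduleAgeEffects = "numeric",
                        moduleCellType = "character",
                        withinModuleCor = "numeric",
                        cellAssocStrength = "numeric",
                        noiseSD = "numeric", transcriptNoiseSD = "numeric",
                        cellTypes = "character",
                        baselineProportions = "numeric",
                        proportionAgeSlopes = "numeric",
                        proportionNoiseSD = "numeric",
                        markersPerCellType = "integer",
                        markerNoiseSD = "numeric",
                        intronicMean = "numeric", intronicSD = "numeric",
                        belowDetectionFraction = "numeric",
                        baselineExpressionRange = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSamples < 4L) msg <- c(msg, "nSamples must be >= 4")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0 ||
      object@ageRange[1L] <= 0)
    msg <- c(msg, "ageRange must be increasing and positive")
  if (length(object@moduleAgeEffects) != object@nModules)
    msg <- c(msg, "moduleAgeEffects must have one value per module")
  if (any(abs(object@moduleAgeEffects) > 1))
    msg <- c(msg, "moduleAgeEffects must lie in [-1, 1]")
  if (length(object@moduleCellType) != object@nModules)
    msg <- c(msg, "moduleCellType must have one value per module")
  if (!all(is.na(object@moduleCellType) |
           object@moduleCellType %in% object@cellTypes))
    msg <- c(msg, "moduleCellType entries must be NA or a known cell type")
  if (object@withinModuleCor <= 0 || object@withinModuleCor >= 1)
    msg <- c(msg, "withinModuleCor must lie strictly in (0, 1)")
  if (object@noiseSD <= 0) msg <- c(msg, "noiseSD must be > 0")
  nct <- length(object@cellTypes)
  if (length(object@baselineProportions) != nct ||
      abs(sum(object@baselineProportions) - 1) > 1e-8 ||
      any(object@baselineProportions <= 0))
    msg <- c(msg, "baselineProportions must be positive and sum to 1")
  if (length(object@proportionAgeSlopes) != nct ||
      length(object@proportionNoiseSD) != nct)
    msg <- c(msg, "per-cell-type parameters must match cellTypes")
  if (object@belowDetectionFraction < 0 || object@belowDetectionFraction >= 1)
    msg <- c(msg, "belowDetectionFraction must lie in [0, 1)")
  if (length(object@transcriptsPerGeneRange) != 2L ||
      object@transcriptsPerGeneRange[1L] < 1L ||
      diff(object@transcriptsPerGeneRange) < 0L)
    msg <- c(msg, "transcriptsPerGeneRange must be an increasing pair >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning of each parameter; arguments
#' override the defaults described there.
#'
#' @param nSamples,ageRange,nModules,genesPerModule,nNoiseGenes
#'   cohort and module layout.
#' @param transcriptsPerGeneRange,moduleAgeEffects,moduleCellType,withinModuleCor
#'   module structure and planted effects.
#' @param cellAssocStrength,noiseSD,transcriptNoiseSD noise / coupling scales.
#' @param cellTypes,baselineProportions,proportionAgeSlopes,proportionNoiseSD
#'   cell-type mixing model.
#' @param markersPerCellType,markerNoiseSD marker-gene layout.
#' @param intronicMean,intronicSD,belowDetectionFraction detection-floor model.
#' @param baselineExpressionRange per-gene baseline expression range.
#' @param seed RNG seed.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 7)
#' sim <- simulateCohort(cfg)
#' sim$cohort
#' @export
simulationConfig <- function(nSamples = 60, ageRange = c(15, 79),
                             nModules = 10, genesPerModule = 40,
                             nNoiseGenes = 200,
                             transcriptsPerGeneRange = c(1, 3),
                             moduleAgeEffects = c(0.7, -0.7, 0.5, -0.5,
                                                  0.3, -0.3, 0, 0, 0, 0),
                             moduleCellType = c(NA, NA, NA, NA, NA, NA,
                                                "neuron", "oligodendrocyte",
                                                NA, NA),
                             withinModuleCor = 0.6,
                             cellAssocStrength = 0.95,
                             noiseSD = 1, transcriptNoiseSD = 0.3,
                             cellTypes = c("neuron", "astrocyte",
                                           "oligodendrocyte", "microglia"),
                             baselineProportions = c(0.40, 0.25, 0.25, 0.10),
                             proportionAgeSlopes = c(-0.0015, 0, 0.0015, 0),
                             proportionNoiseSD = c(0.09, 0.03, 0.09, 0.02),
                             markersPerCellType = 25,
                             markerNoiseSD = 0.2,
                             intronicMean = 1.0, intronicSD = 0.3,
                             belowDetectionFraction = 0.05,
                             baselineExpressionRange = c(5, 9),
                             seed = 1) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples), ageRange = as.numeric(ageRange),
      nModules = as.integer(nModules),
      genesPerModule = as.integer(genesPerModule),
      nNoiseGenes = as.integer(nNoiseGenes),
      transcriptsPerGeneRange = as.integer(transcriptsPerGeneRange),
      moduleAgeEffects = as.numeric(moduleAgeEffects),
      moduleCellType = as.character(moduleCellType),
      withinModuleCor = as.numeric(withinModuleCor),
      cellAssocStrength = as.numeric(cellAssocStrength),
      noiseSD = as.numeric(noiseSD),
      transcriptNoiseSD = as.numeric(transcriptNoiseSD),
      cellTypes = as.character(cellTypes),
      baselineProportions = as.numeric(baselineProportions),
      proportionAgeSlopes = as.numeric(proportionAgeSlopes),
      proportionNoiseSD = as.numeric(proportionNoiseSD),
      markersPerCellType = as.integer(markersPerCellType),
      markerNoiseSD = as.numeric(markerNoiseSD),
      intronicMean = as.numeric(intronicMean),
      intronicSD = as.numeric(intronicSD),
      belowDetectionFraction = as.numeric(belowDetectionFraction),
      baselineExpressionRange = as.numeric(baselineExpressionRange),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples, ages",
      paste(object@ageRange, collapse = "-"), "\n")
  cat(" ", object@nModules, "modules x", object@genesPerModule, "genes +",
      object@nNoiseGenes, "noise genes +",
      object@markersPerCellType, "markers x",
      length(object@cellTypes), "cell types\n")
  cat("  seed", object@seed, "\n")
  invisible(NULL)
})

#' Ground truth of a simulated cohort
#'
#' @slot transcriptModule planted module label per transcript (`"M01"`...,
#'   `"marker_<celltype>"`, `"noise"`).
#' @slot geneModule planted module label per gene.
#' @slot mechanism per-gene age-effect mechanism: `"direct"`,
#'   `"cellularity"` or `"none"` (mutually exclusive).
#' @slot trueProportions cell types x samples matrix of true mixing
#'   proportions (columns sum to 1).
#' @slot factors planted module latent factors (modules x samples).
#' @slot markers named list, cell type -> marker gene symbols.
#' @slot belowDetection transcripts planted below the detection floor.
#' @slot moduleAgeEffects,moduleCellType copies of the planted design.
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(transcriptModule = "character",
                        geneModule = "character",
                        mechanism = "character",
                        trueProportions = "matrix",
                        factors = "matrix",
                        markers = "list",
                        belowDetection = "character",
                        moduleAgeEffects = "numeric",
                        moduleCellType = "character"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@transcriptModule), "transcripts,",
      length(object@mechanism), "genes,",
      nrow(object@factors), "planted modules\n")
  cat("  mechanisms:",
      paste(sprintf("%s=%d", names(table(object@mechanism)),
                    table(object@mechanism)), collapse = " "), "\n")
  invisible(NULL)
})

# standardize to zero mean / unit SD (population of the sample)
.zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# standardized residual of y after removing drivers (with intercept)
.orthonormalize <- function(y, drivers) {
  if (is.null(drivers) || NCOL(drivers) == 0L) return(.zscore(y))
  fit <- stats::lm.fit(cbind(1, drivers), y)
  .zscore(fit$residuals)
}

#' Simulate a brain-aging cohort with known ground truth
#'
#' Generates a transcripts-by-samples expression matrix on a normalized log
#' scale. The generative model: (1) donor ages uniform over the configured
#' range; (2) true cell-type proportions drift linearly with age plus
#' biological noise, clipped at 0.01 and renormalized to the simplex;
#' (3) each module has a latent factor built from standardized age and/or
#' its cell type's standardized proportion plus orthogonalized noise, so
#' the realized factor-age correlation matches the configured target;
#' (4) transcripts load on their gene's signal (`lambda = sqrt(withinModuleCor)`
#' on the module factor) with transcript-specific noise; (5) marker genes
#' track their cell type's proportion with high fidelity; (6) noise genes
#' are pure noise; (7) per-sample intronic background summaries are drawn
#' and a configured fraction of non-marker transcripts is replaced by
#' background-level noise so the detection filter has work to do.
#'
#' Deterministic given `config@seed` (same seed, bit-identical output).
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `cohort` (an [AgingCohort-class] annotated to
#'   genes) and `truth` (a [GroundTruth-class]).
#' @examples
#' sim <- simulateCohort(simulationConfig(seed = 42))
#' table(sim$truth@transcriptModule)[1:3]
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nSamples
  ages <- runif(n, config@ageRange[1L], config@ageRange[2L])
  sample_ids <- sprintf("S%03d", seq_len(n))
  z_age <- .zscore(ages)

  ## --- cell-type proportions: baseline + slope*(age - mean) + noise ---
  nct <- length(config@cellTypes)
  raw <- matrix(NA_real_, nct, n,
                dimnames = list(config@cellTypes, sample_ids))
  for (k in seq_len(nct)) {
    # biological noise drawn orthogonal to age so the planted proportion-age
    # coupling is realized at its designed strength in-sample
    raw[k, ] <- config@baselineProportions[k] +
      config@proportionAgeSlopes[k] * (ages - mean(ages)) +
      config@proportionNoiseSD[k] * .orthonormalize(rnorm(n), z_age)
  }
  raw <- pmax(raw, 0.01)
  totals <- colSums(raw)
  if (any(totals <= 0.05))
    stop("infeasible cell-type proportions: slopes/noise drove total mass to ~0")
  props <- sweep(raw, 2L, totals, "/")

  ## --- module latent factors ---
  nm <- config@nModules
  factors <- matrix(NA_real_, nm, n,
                    dimnames = list(sprintf("M%02d", seq_len(nm)), sample_ids))
  for (m in seq_len(nm)) {
    alpha <- config@moduleAgeEffects[m]
    ct <- config@moduleCellType[m]
    drivers <- NULL
    f <- rep(0, n)
    if (alpha != 0) {
      drivers <- cbind(drivers, z_age)
      f <- f + alpha * z_age
    }
    if (!is.na(ct)) {
      z_prop <- .zscore(props[ct, ])
      drivers <- cbind(drivers, z_prop)
      f <- f + config@cellAssocStrength * z_prop
    }
    # remaining variance after the planted drivers (in-sample orthogonal)
    v <- 1 - alpha^2
    if (!is.na(ct)) {
      rho <- if (alpha != 0) cor(z_age, .zscore(props[ct, ])) else 0
      v <- v - config@cellAssocStrength^2 -
        2 * alpha * config@cellAssocStrength * rho
    }
    if (v < 0)
      stop(sprintf("module %d: planted effects leave negative residual variance", m))
    f <- f + sqrt(v) * .orthonormalize(rnorm(n), drivers)
    factors[m, ] <- f
  }

  ## --- gene and transcript layout ---
  lambda <- sqrt(config@withinModuleCor)
  gene_ids <- character(0); gene_module <- character(0)
  mechanism <- character(0)
  gene_signal <- list()

  mod_mech <- ifelse(config@moduleAgeEffects != 0, "direct",
                     ifelse(!is.na(config@moduleCellType), "cellularity",
                            "none"))
  gidx <- 0L
  for (m in seq_len(nm)) {
    for (g in seq_len(config@genesPerModule)) {
      gidx <- gidx + 1L
      id <- sprintf("GENE%04d", gidx)
      gene_ids <- c(gene_ids, id)
      gene_module <- c(gene_module, sprintf("M%02d", m))
      mechanism <- c(mechanism, mod_mech[m])
      gene_signal[[id]] <- lambda * factors[m, ] +
        sqrt(1 - lambda^2) * rnorm(n)
    }
  }
  markers <- list()
  for (ct in config@cellTypes) {
    ids <- character(config@markersPerCellType)
    z_prop <- .zscore(props[ct, ])
    for (g in seq_len(config@markersPerCellType)) {
      gidx <- gidx + 1L
      id <- sprintf("GENE%04d", gidx)
      ids[g] <- id
      gene_ids <- c(gene_ids, id)
      gene_module <- c(gene_module, paste0("marker_", ct))
      mechanism <- c(mechanism, "cellularity")
      gene_signal[[id]] <- z_prop + config@markerNoiseSD * rnorm(n)
    }
    markers[[ct]] <- ids
  }
  n_struct_genes <- gidx
  for (g in seq_len(config@nNoiseGenes)) {
    gidx <- gidx + 1L
    id <- sprintf("GENE%04d", gidx)
    gene_ids <- c(gene_ids, id)
    gene_module <- c(gene_module, "noise")
    mechanism <- c(mechanism, "none")
    gene_signal[[id]] <- rnorm(n)
  }
  names(gene_module) <- gene_ids
  names(mechanism) <- gene_ids

  ## --- transcripts: module/noise genes get 1..k isoforms, markers one ---
  tpg <- config@transcriptsPerGeneRange
  is_marker_gene <- grepl("^marker_", gene_module)
  n_tx_per_gene <- ifelse(is_marker_gene, 1L,
                          sample(seq(tpg[1L], tpg[2L]),
                                 length(gene_ids), replace = TRUE))
  offsets <- runif(length(gene_ids), config@baselineExpressionRange[1L],
                   config@baselineExpressionRange[2L])
  names(offsets) <- gene_ids

  tx_ids <- character(0); tx_gene <- character(0)
  rows <- vector("list", sum(n_tx_per_gene))
  r <- 0L
  for (i in seq_along(gene_ids)) {
    id <- gene_ids[i]
    for (k in seq_len(n_tx_per_gene[i])) {
      r <- r + 1L
      tx <- sprintf("%s.%d", id, k)
      tx_ids <- c(tx_ids, tx); tx_gene <- c(tx_gene, id)
      rows[[r]] <- offsets[i] + config@noiseSD *
        (gene_signal[[id]] + config@transcriptNoiseSD * rnorm(n))
    }
  }
  expr <- do.call(rbind, rows)
  dimnames(expr) <- list(tx_ids, sample_ids)
  names(tx_gene) <- tx_ids
  tx_module <- gene_module[tx_gene]
  names(tx_module) <- tx_ids

  ## --- intronic background floor + planted undetectable transcripts ---
  im <- rnorm(n, config@intronicMean, 0.1)
  isd <- abs(rnorm(n, config@intronicSD, 0.05))
  eligible <- tx_ids[!grepl("^marker_", tx_module)]
  n_bd <- round(config@belowDetectionFraction * length(eligible))
  below <- if (n_bd > 0L) sort(sample(eligible, n_bd)) else character(0)
  if (n_bd > 0L)
    expr[below, ] <- matrix(rnorm(n_bd * n, rep(im, each = n_bd),
                                  rep(isd, each = n_bd)), n_bd, n)

  metadata <- data.frame(
    age = ages,
    sex = ifelse(rbinom(n, 1L, 0.25) == 1L, "male", "female"),
    rin = runif(n, 6, 9.5),
    pmi = runif(n, 3, 30),
    batch = paste0("batch", sample(rep(1:3, length.out = n))),
    intronic_mean = im,
    intronic_sd = isd,
    row.names = sample_ids, stringsAsFactors = FALSE)

  cohort <- AgingCohort(expr, metadata, annotation = tx_gene)
  truth <- new("GroundTruth",
               transcriptModule = tx_module, geneModule = gene_module,
               mechanism = mechanism, trueProportions = props,
               factors = factors, markers = markers,
               belowDetection = below,
               moduleAgeEffects = config@moduleAgeEffects,
               moduleCellType = config@moduleCellType)
  list(cohort = cohort, truth = truth)
}

#' Simulate a gene-level replication dataset on a second platform
#'
#' Draws an independent cohort from the same generative process (the module
#' layout, per-gene mechanism and loadings are deterministic functions of
#' the configuration, so ground truth is shared across seeds), collapses it
#' to one transcript per gene by highest mean expression, restricts it to a
#' random gene subset, and adds platform noise. With the original cohort's
#' seed, `geneSubsetFraction = 1` and `platformNoiseSD = 0`, the output is
#' exactly the collapsed original.
#'
#' @param config the [SimulationConfig-class] shared with the first cohort.
#' @param geneSubsetFraction fraction of genes retained, in (0, 1].
#' @param platformNoiseSD SD of additive platform noise (log units).
#' @param seed seed for the replicate cohort (a different seed gives an
#'   independently ascertained cohort).
#' @return list with `cohort` (gene-level [AgingCohort-class]) and `truth`
#'   (the replicate's [GroundTruth-class]).
#' @export
simulateSecondPlatform <- function(config, geneSubsetFraction = 1,
                                   platformNoiseSD = 0.5, seed) {
  stopifnot(is(config, "SimulationConfig"))
  if (geneSubsetFraction <= 0 || geneSubsetFraction > 1)
    stop("geneSubsetFraction must lie in (0, 1]")
  cfg <- config
  cfg@seed <- as.integer(seed)
  sim <- simulateCohort(cfg)
  gene_cohort <- collapseToGene(sim$cohort)
  genes <- rownames(gene_cohort)
  n_keep <- ceiling(geneSubsetFraction * length(genes))
  if (n_keep < 1L) stop("gene subset is empty")
  keep <- if (n_keep < length(genes)) sort(sample(genes, n_keep)) else genes
  gene_cohort <- gene_cohort[keep, ]
  if (platformNoiseSD > 0) {
    m <- exprValues(gene_cohort)
    m <- m + matrix(rnorm(length(m), 0, platformNoiseSD),
                    nrow(m), ncol(m))
    ann <- SummarizedExperiment::rowData(gene_cohort)$gene_symbol
    names(ann) <- rownames(gene_cohort)
    noisy <- AgingCohort(
      m, as.data.frame(SummarizedExperiment::colData(gene_cohort)),
      annotation = ann)
    SummarizedExperiment::rowData(noisy)$transcript_id <-
      SummarizedExperiment::rowData(gene_cohort)$transcript_id
    gene_cohort <- noisy
  }
  list(cohort = gene_cohort, truth = sim$truth)
}
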