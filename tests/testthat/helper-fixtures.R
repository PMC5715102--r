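# Shared fixtures, built once per test run. The default simulated cohort
# (60 samples, 10 planted modules x 40 genes, 200 noise genes, seed 1) and
# the network built from it at the desk-scale parameters (power 6,
# minModuleSize 10, cutHeight 0.90) are reused across test files.

.fixtures <- new.env(parent = emptyenv())

defaultSim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulateCohort(simulationConfig(seed = 1))
  .fixtures$sim
}

filteredCohort <- function() {
  if (is.null(.fixtures$filtered))
    .fixtures$filtered <- filterDetected(defaultSim()$cohort)
  .fixtures$filtered
}

defaultNetwork <- function() {
  if (is.null(.fixtures$net))
    .fixtures$net <- buildNetwork(filteredCohort(), power = 6,
                                  minModuleSize = 10, cutHeight = 0.90)
  .fixtures$net
}

defaultReferences <- function() {
  if (is.null(.fixtures$refs))
    .fixtures$refs <- buildReferenceSignals(collapseToGene(filteredCohort()),
                                            defaultSim()$truth@markers)
  .fixtures$refs
}

# uncorrected and neuron-corrected transcript-age association tables
defaultCorrectionPair <- function() {
  if (is.null(.fixtures$pair)) {
    fc <- filteredCohort()
    refs <- defaultReferences()
    corrected <- correctForNeurons(fc, refs["neuron", ])
    before <- suppressWarnings(transcriptAgeAssociations(fc))
    after <- suppressWarnings(transcriptAgeAssociations(corrected))
    after <- after[match(before$transcript_id, after$transcript_id), ]
    .fixtures$pair <- list(before = before, after = after)
  }
  .fixtures$pair
}

# small well-formed expression matrix for I/O and filter tests
toyMatrix <- function() {
  matrix(c(2, 2, 2, 2,
           2, 2, 2, 1),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("txA", "txB"), paste0("s", 1:4)))
}
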