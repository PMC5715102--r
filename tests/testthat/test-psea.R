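test_that("reference signals reproduce the hand-worked scaling example", {
  m <- rbind(mk1 = c(2, 4), mk2 = c(4, 8), other = c(1, 1))
  colnames(m) <- c("s1", "s2")
  refs <- buildReferenceSignals(m, list(neuron = c("mk1", "mk2")))
  expect_equal(unname(refs["neuron", ]), c(2 / 3, 4 / 3))
  expect_equal(mean(refs["neuron", ]), 1)
  # a single constant marker gives the unit reference
  refs2 <- suppressWarnings(
    buildReferenceSignals(m, list(glia = "other")))
  expect_equal(unname(refs2["glia", ]), c(1, 1))
})

test_that("reference signals are scale-invariant and validate their inputs", {
  set.seed(21)
  m <- matrix(abs(rnorm(5 * 8, 6)), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  mk <- list(neuron = c("g1", "g2"), astro = c("g3"))
  r1 <- buildReferenceSignals(m, mk)
  m2 <- m; m2["g1", ] <- 3.7 * m2["g1", ]
  r2 <- buildReferenceSignals(m2, mk)
  expect_lt(max(abs(r1 - r2)), 1e-12)
  expect_lt(max(abs(rowMeans(r1) - 1)), 1e-12)
  expect_warning(buildReferenceSignals(m, list(neuron = c("g1", "gX"))),
                 "dropped")
  expect_error(buildReferenceSignals(m, list(oligo = "gZ")), "no marker")
  expect_error(markerSets(list(a = "g1", b = "g1")), "more than one")
})

test_that("estimated neuronal signal tracks the true neuron fraction", {
  sim <- defaultSim()
  refs <- defaultReferences()
  for (ct in rownames(sim$truth@trueProportions)) {
    expect_gte(cor(refs[ct, ], sim$truth@trueProportions[ct, ]), 0.9)
  }
})

test_that("cell-contribution regression matches a normal-equations oracle", {
  set.seed(31)
  refs <- matrix(abs(rnorm(4 * 20, 1, 0.2)), 4, 20,
                 dimnames = list(c("neuron", "astro", "oligo", "micro"),
                                 paste0("s", 1:20)))
  refs <- refs / rowMeans(refs)
  m <- rbind(pure = refs["neuron", ],
             mix = 2 + 0.5 * refs["astro", ] + rnorm(20, 0, 0.05),
             noise = rnorm(20, 5))
  colnames(m) <- colnames(refs)
  fit <- estimateCellContributions(m, refs)
  expect_equal(unname(fit$coefficients["pure", "neuron"]), 1,
               tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["pure", "intercept"]), 0,
               tolerance = 1e-9)
  expect_equal(unname(fit$r_squared["pure"]), 1, tolerance = 1e-9)
  # independent oracle: solve the normal equations directly
  X <- cbind(1, t(refs))
  beta <- solve(t(X) %*% X, t(X) %*% m["mix", ])
  expect_lt(max(abs(fit$coefficients["mix", ] - as.vector(beta))), 1e-9)
  # collinear references are refused
  bad <- refs; bad["micro", ] <- 2 * bad["neuron", ]
  expect_error(estimateCellContributions(m, bad), "collinear")
})

test_that("a noise gene's fit stays below the permutation null quantile", {
  set.seed(41)
  sim <- defaultSim()
  refs <- defaultReferences()
  m <- rbind(noisegene = rnorm(ncol(refs), 5))
  colnames(m) <- colnames(refs)
  observed <- estimateCellContributions(m, refs)$r_squared[["noisegene"]]
  perms <- vapply(1:200, function(i) {
    pr <- refs[, sample(ncol(refs))]
    colnames(pr) <- colnames(refs)
    estimateCellContributions(m, pr)$r_squared[["noisegene"]]
  }, numeric(1))
  expect_lte(observed, quantile(perms, 0.95))
})

test_that("neuron correction residualizes exactly and preserves scale", {
  set.seed(51)
  ref <- abs(rnorm(12, 1, 0.2))
  m <- rbind(mediated = 3 + 2 * ref,
             ortho = rnorm(12),
             mixed = 1 + ref + rnorm(12))
  m["ortho", ] <- m["ortho", ] -
    (cov(m["ortho", ], ref) / var(ref)) * (ref - mean(ref))  # exact orthogonality
  colnames(m) <- paste0("s", 1:12)
  cm <- correctForNeurons(m, ref)
  expect_lt(max(abs(cm["mediated", ] - mean(m["mediated", ]))), 1e-9)
  expect_lt(max(abs(cm["ortho", ] - m["ortho", ])), 1e-9)
  expect_lt(max(abs(rowMeans(cm) - rowMeans(m))), 1e-9)     # grand means kept
  for (i in rownames(cm)) {
    if (sd(cm[i, ]) > 1e-12) expect_lt(abs(cor(cm[i, ], ref)), 1e-9)
  }
  expect_error(correctForNeurons(m, rep(1, 12)), "constant")
})

test_that("all corrected transcripts decorrelate from the reference on the cohort", {
  fc <- filteredCohort()
  refs <- defaultReferences()
  cm <- correctForNeurons(fc, refs["neuron", ])
  x <- exprValues(cm)
  r <- suppressWarnings(cor(t(x), refs["neuron", ]))
  expect_lt(max(abs(r), na.rm = TRUE), 1e-9)
})

test_that("neuron correction separates cellularity-mediated from direct effects", {
  sim <- defaultSim()
  pair <- defaultCorrectionPair()
  gs <- geneSymbols(filteredCohort())[pair$before$transcript_id]
  gm <- sim$truth@geneModule[gs]
  retention <- function(mods) {
    i <- gm %in% mods
    mean(abs(pair$after$R[i])) / mean(abs(pair$before$R[i]))
  }
  expect_lt(retention("M07"), 0.5)            # neuron-mediated module collapses
  expect_gte(retention(paste0("M0", 1:6)), 0.7)  # direct effects survive
})

test_that("before/after comparison counts drops per module correctly", {
  sim <- defaultSim()
  pair <- defaultCorrectionPair()
  gs <- geneSymbols(filteredCohort())[pair$before$transcript_id]
  labels <- stats::setNames(sim$truth@geneModule[gs],
                            pair$before$transcript_id)
  neuron_markers_tx <- pair$before$transcript_id[
    labels == "marker_neuron"]
  cmp <- compareCorrectedAssociations(pair$before, pair$after, labels,
                                      exclude = neuron_markers_tx)
  s <- cmp$summary
  expect_false("marker_neuron" %in% s$module)   # circular features excluded
  drops <- s$n_sig_before - s$n_sig_after
  names(drops) <- s$module
  planted <- paste0("M", sprintf("%02d", 1:10))
  # the neuron-mediated module loses the most; null modules barely move
  expect_identical(names(which.max(drops[planted])), "M07")
  expect_true(all(drops["M07"] > drops[c("M09", "M10")]))

  ident <- compareCorrectedAssociations(pair$before, pair$before, labels)
  expect_true(all(ident$summary$n_sig_before == ident$summary$n_sig_after))
  expect_true(all(abs(ident$summary$mean_R_before -
                        ident$summary$mean_R_after) < 1e-15))

  perm <- sample(nrow(pair$before))
  cmp2 <- compareCorrectedAssociations(pair$before[perm, ], pair$after,
                                       labels)
  s2 <- cmp2$summary[match(s$module, cmp2$summary$module), ]
  expect_identical(s2$n_sig_before, s$n_sig_before)

  bad <- pair$after[-1, ]
  expect_error(compareCorrectedAssociations(pair$before, bad, labels),
               "universe")
})
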