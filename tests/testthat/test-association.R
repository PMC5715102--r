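# streaming two-pass Pearson correlation, independent of stats::cor
corOracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

test_that("transcript-age associations recover exact lines and match oracles", {
  age <- c(21, 35, 47, 52, 66, 73)
  m <- rbind(lin = 2 * age + 3,
             anti = -0.5 * age + 10,
             noise = c(4, 2, 7, 1, 6, 3))
  colnames(m) <- paste0("s", 1:6)
  tab <- transcriptAgeAssociations(m, age)
  i <- match("lin", tab$transcript_id)
  expect_equal(tab$R[i], 1)
  expect_equal(tab$slope[i], 2)
  expect_equal(tab$intercept[i], 3)
  expect_equal(tab$R[tab$transcript_id == "anti"], -1)

  set.seed(8)
  m2 <- matrix(rnorm(50 * 12), 50, 12,
               dimnames = list(sprintf("t%02d", 1:50), paste0("s", 1:12)))
  age2 <- runif(12, 20, 80)
  tab2 <- transcriptAgeAssociations(m2, age2)
  for (j in c(1, 17, 50)) {
    id <- sprintf("t%02d", j)
    expect_lt(abs(tab2$R[tab2$transcript_id == id] -
                    corOracle(m2[id, ], age2)), 1e-12)
    ct <- cor.test(m2[id, ], age2)
    expect_equal(tab2$p_nominal[tab2$transcript_id == id],
                 unname(ct$p.value), tolerance = 1e-12)
  }
})

test_that("zero-variance transcripts are excluded with a warning", {
  age <- c(20, 30, 40, 50)
  m <- rbind(ok = c(1, 2, 3, 5), flat = rep(2, 4))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(tab <- transcriptAgeAssociations(m, age), "flat")
  expect_identical(tab$transcript_id, "ok")
})

test_that("confidence bands match the lm prediction-interval oracle", {
  set.seed(5)
  age <- runif(15, 20, 80)
  m <- rbind(t1 = 0.05 * age + rnorm(15, 0, 1))
  colnames(m) <- paste0("s", 1:15)
  tab <- transcriptAgeAssociations(m, age)
  grid <- c(25, 50, 75)
  band <- confidenceBand(tab, "t1", grid)
  fit <- lm(y ~ x, data.frame(x = age, y = m["t1", ]))
  pred <- predict(fit, newdata = data.frame(x = grid),
                  interval = "confidence", level = 0.95)
  expect_lt(max(abs(band$fit - pred[, "fit"])), 1e-9)
  expect_lt(max(abs(band$lower - pred[, "lwr"])), 1e-9)
  expect_lt(max(abs(band$upper - pred[, "upr"])), 1e-9)
})

test_that("BH adjustment is monotone and signs agree with slopes", {
  tab <- suppressWarnings(transcriptAgeAssociations(filteredCohort()))
  ord_nom <- order(tab$p_nominal)
  expect_true(!is.unsorted(tab$p_adjusted[ord_nom]))
  expect_true(all(tab$p_adjusted >= tab$p_nominal - 1e-15))
  expect_true(all(sign(tab$R) == sign(tab$slope)))
})

test_that("eigengene-trait correlations handle exact, null and degenerate traits", {
  s <- paste0("s", 1:12)
  age <- seq(20, 75, length.out = 12)
  me <- rbind(lin = (age - mean(age)) / sd(age),
              other = rnorm(12))
  colnames(me) <- s
  md <- data.frame(age = age, sex = rep(c("female", "male"), 6),
                   rin = rep(7, 12), pmi = runif(12, 5, 20),
                   batch = rep(c("b1", "b2", "b3"), 4),
                   row.names = s)
  w <- capture_warnings(tab <- eigengeneTraitAssociations(me, md))
  expect_true(any(grepl("constant", w)))
  lin_age <- tab[tab$module == "lin" & tab$trait == "age", ]
  expect_equal(lin_age$R, 1)
  expect_lt(lin_age$p_nominal, 1e-12)
  rin_row <- tab[tab$module == "lin" & tab$trait == "rin", ]
  expect_equal(rin_row$R, 0)
  expect_equal(rin_row$p_nominal, 1)
  expect_true(rin_row$degenerate)
  batch_row <- tab[tab$module == "lin" & tab$trait == "batch", ]
  expect_true(batch_row$level %in% c("b1", "b2", "b3"))

  # n = 3 with R exactly 0 gives p = 1
  me3 <- rbind(flat0 = c(-1, 0, 1))
  colnames(me3) <- paste0("x", 1:3)
  md3 <- data.frame(age = c(30, 10, 30), sex = rep("female", 3),
                    rin = c(6, 7, 8), pmi = c(1, 2, 3), batch = "b1",
                    row.names = paste0("x", 1:3))
  tab3 <- suppressWarnings(eigengeneTraitAssociations(me3, md3,
                                                      traits = "age"))
  expect_equal(tab3$R, 0)
  expect_equal(tab3$p_nominal, 1)
})

test_that("planted module-age effects are recovered with BH significance", {
  sim <- defaultSim(); fc <- filteredCohort()
  eg <- moduleEigengenes(exprValues(fc),
                         sim$truth@transcriptModule[rownames(fc)])
  tab <- eigengeneTraitAssociations(eg$eigengenes, sim$cohort,
                                    traits = c("age", "rin", "pmi"))
  m02 <- tab[tab$module == "M02" & tab$trait == "age", ]
  expect_gte(m02$R, -0.85); expect_lte(m02$R, -0.5)
  expect_true(m02$significant)
  for (mod in c("M09", "M10")) {
    null_row <- tab[tab$module == mod & tab$trait == "age", ]
    expect_lt(abs(null_row$R), 0.35)
  }
})

test_that("significant-association counting splits by sign and permutes freely", {
  tab <- data.frame(R = c(0.5, -0.4, -0.2),
                    p_nominal = c(0.01, 0.2, 0.04),
                    p_adjusted = c(0.03, 0.6, 0.12))
  expect_identical(countSignificant(tab, 0.05, "nominal"),
                   c(positive = 1L, negative = 1L))
  expect_identical(countSignificant(tab[sample(3), ], 0.05, "nominal"),
                   c(positive = 1L, negative = 1L))
  expect_identical(countSignificant(tab, 0.001, "nominal"),
                   c(positive = 0L, negative = 0L))
  expect_identical(countSignificant(tab, 0.05, "adjusted"),
                   c(positive = 1L, negative = 0L))
  expect_error(countSignificant(tab[0, ]), "empty")
})

test_that("a planted-null cohort is calibrated at the nominal type-I level", {
  cfg <- simulationConfig(nSamples = 60, nModules = 1, genesPerModule = 2,
                          moduleAgeEffects = 0,
                          moduleCellType = NA_character_,
                          nNoiseGenes = 500, markersPerCellType = 2,
                          belowDetectionFraction = 0, seed = 3)
  sim <- simulateCohort(cfg)
  noise_tx <- names(sim$truth@transcriptModule)[
    sim$truth@transcriptModule == "noise"]
  tab <- transcriptAgeAssociations(exprValues(sim$cohort)[noise_tx, ],
                                   sampleAges(sim$cohort))
  expect_gte(nrow(tab), 900)
  frac <- mean(tab$p_nominal < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  expect_lte(mean(tab$p_adjusted < 0.05), 0.07)
})
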