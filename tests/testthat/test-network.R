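# triple-loop TOM oracle, deliberately independent of the matrix-algebra path
tomOracle <- function(a) {
  n <- nrow(a)
  k <- colSums(a) - 1
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

randomAdjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

test_that("signed adjacency matches its formula at the worked endpoints", {
  # rows with sample correlations exactly +1, -1 and 0.5
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1),
             d = c(1, 3, 2))
  colnames(m) <- paste0("s", 1:3)
  a6 <- signedAdjacency(m, power = 6)
  expect_equal(a6["a", "b"], 1)                       # cor = 1
  expect_equal(a6["a", "c"], 0)                       # cor = -1
  expect_equal(a6["a", "d"], 0.177978515625)          # 0.75^6, cor = 0.5
  a1 <- signedAdjacency(m, power = 1)
  expect_equal(a1["a", "d"], 0.75)
  expect_error(signedAdjacency(rbind(m, e = c(5, 5, 5)), 6), "e")
})

test_that("raising the power never increases adjacency below cor 1", {
  set.seed(42)
  m <- matrix(rnorm(80), 8, 10,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  a2 <- signedAdjacency(m, 2); a6 <- signedAdjacency(m, 6)
  off <- upper.tri(a2)
  expect_true(all(a6[off] <= a2[off] + 1e-15))
})

test_that("topological overlap reproduces hand-computed and degenerate cases", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(paste0("t", 1:3), paste0("t", 1:3))
  tom <- topologicalOverlap(a)
  expect_equal(tom["t1", "t2"], 0.5)                  # (0.25+0.5)/(1+1-0.5)
  expect_equal(diag(tom), c(t1 = 1, t2 = 1, t3 = 1))
  iso <- diag(1, 2)
  dimnames(iso) <- list(c("a", "b"), c("a", "b"))
  expect_equal(topologicalOverlap(iso)["a", "b"], 0)  # isolated pair
})

test_that("matrix-algebra TOM agrees with a triple-loop oracle", {
  set.seed(7)
  for (rep in 1:20) {
    a <- randomAdjacency(8)
    expect_lt(max(abs(topologicalOverlap(a) - tomOracle(a))), 1e-12)
  }
})

test_that("module detection recovers two planted blocks and leaves noise grey", {
  set.seed(11)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  lam <- sqrt(0.8)
  block <- function(f, k, prefix) {
    m <- t(vapply(seq_len(k), function(i) lam * f + sqrt(1 - lam^2) * rnorm(n),
                  numeric(n)))
    rownames(m) <- sprintf("%s%02d", prefix, seq_len(k))
    m
  }
  m <- rbind(block(f1, 50, "a"), block(f2, 50, "b"))
  colnames(m) <- paste0("s", seq_len(n))
  tom <- topologicalOverlap(signedAdjacency(m, 6))
  lab <- detectModules(1 - tom, minModuleSize = 10, cutHeight = 0.9)
  expect_identical(length(setdiff(unique(lab), "grey")), 2L)
  truth <- rep(c("A", "B"), each = 50)
  expect_gte(mclust::adjustedRandIndex(lab, truth), 0.9)

  noise <- matrix(rnorm(100 * n), 100, n,
                  dimnames = list(sprintf("x%03d", 1:100),
                                  paste0("s", seq_len(n))))
  ntom <- topologicalOverlap(signedAdjacency(noise, 6))
  nlab <- detectModules(1 - ntom, minModuleSize = 10, cutHeight = 0.9)
  expect_gte(mean(nlab == "grey"), 0.9)

  expect_warning(all_grey <- detectModules(1 - tom, minModuleSize = 101),
                 "all grey")
  expect_true(all(all_grey == "grey"))
})

test_that("eigengenes behave on rank-1, permutation and singleton cases", {
  s <- paste0("s", 1:6)
  x <- c(1, 3, 2, 5, 4, 6)
  m <- rbind(t1 = x, t2 = 2 * x + 1, t3 = rnorm(6))
  colnames(m) <- s
  eg <- moduleEigengenes(m, c(t1 = "blue", t2 = "blue", t3 = "grey"))
  expect_equal(eg$varianceExplained[["blue"]], 1)      # identical profiles
  expect_equal(sum(eg$eigengenes["blue", ]^2), 1)      # unit norm
  expect_gte(cor(eg$eigengenes["blue", ], x), 0.999)   # sign convention

  sim <- defaultSim(); fc <- filteredCohort()
  labels <- sim$truth@transcriptModule[rownames(fc)]
  eg1 <- moduleEigengenes(exprValues(fc), labels)
  shuffled <- exprValues(fc)[sample(rownames(fc)), ]
  eg2 <- moduleEigengenes(shuffled, labels[rownames(shuffled)])
  expect_lt(max(abs(eg1$eigengenes[rownames(eg2$eigengenes), ] -
                      eg2$eigengenes)), 1e-9)

  one <- moduleEigengenes(m, c(t1 = "red", t2 = "grey", t3 = "grey"))
  expect_equal(one$varianceExplained[["red"]], 1)
  expect_equal(abs(cor(one$eigengenes["red", ], x)), 1)
})

test_that("planted module factors are recovered by their eigengenes", {
  sim <- defaultSim(); fc <- filteredCohort()
  eg <- moduleEigengenes(exprValues(fc),
                         sim$truth@transcriptModule[rownames(fc)])
  for (m in rownames(sim$truth@factors)) {
    expect_gte(abs(cor(eg$eigengenes[m, ], sim$truth@factors[m, ])), 0.9)
  }
})

test_that("connectivity and hub calling follow the summation and tie rules", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(c("t2", "t1", "t3"), c("t2", "t1", "t3"))
  ch <- connectivityAndHubs(a, c(t2 = "blue", t1 = "blue", t3 = "blue"))
  expect_equal(unname(ch$kTotal), rep(1, 3))
  expect_equal(ch$kWithin, ch$kTotal)
  expect_identical(unname(ch$hubs["blue"]), "t1")      # tie -> smallest ID

  ch2 <- connectivityAndHubs(a, c(t2 = "blue", t1 = "blue", t3 = "red"))
  expect_equal(unname(ch2$kWithin["t3"]), 0)           # alone in its label

  net <- defaultNetwork()
  expect_true(all(net@kWithin <= net@kTotal + 1e-9))
})

test_that("renaming transcripts changes no numeric network output", {
  set.seed(3)
  m <- matrix(rnorm(15 * 12), 15, 12,
              dimnames = list(sprintf("t%02d", 1:15), paste0("s", 1:12)))
  m2 <- m; rownames(m2) <- sprintf("zz%02d", 1:15)
  n1 <- buildNetwork(m, power = 6, minModuleSize = 3, cutHeight = 0.95)
  n2 <- buildNetwork(m2, power = 6, minModuleSize = 3, cutHeight = 0.95)
  expect_equal(unname(n1@adjacency), unname(n2@adjacency))
  expect_equal(unname(n1@tom), unname(n2@tom))
  expect_identical(unname(n1@moduleLabels), unname(n2@moduleLabels))
  expect_equal(unname(n1@kTotal), unname(n2@kTotal))
})

test_that("adjacency and TOM are symmetric and bounded on the default cohort", {
  net <- defaultNetwork()
  expect_lt(max(abs(net@adjacency - t(net@adjacency))), 1e-12)
  expect_lt(max(abs(net@tom - t(net@tom))), 1e-12)
  expect_true(all(net@adjacency >= 0 & net@adjacency <= 1))
  expect_true(all(net@tom >= 0 & net@tom <= 1))
  expect_true(all(rowSums(net@eigengenes^2) - 1 < 1e-9))
})

test_that("soft-threshold selection handles degenerate and regular inputs", {
  # perfectly correlated transcripts: all k identical, fit 0 with a warning
  base <- c(1, 4, 2, 6, 3, 5)
  m <- rbind(a = base, b = 2 * base, c = base + 3, d = 3 * base - 1)
  colnames(m) <- paste0("s", 1:6)
  w <- capture_warnings(sf <- pickSoftThreshold(m, powers = c(1, 2)))
  expect_true(any(grepl("identical", w)))
  expect_true(any(grepl("no candidate power", w)))
  expect_true(all(sf@table$fit == 0))

  fc <- filteredCohort()
  sf2 <- suppressWarnings(pickSoftThreshold(exprValues(fc)))
  expect_true(all(sf2@table$fit <= 1))
  expect_true(chosenPower(sf2) %in% sf2@table$power)
  reached <- sf2@table$power[sf2@table$fit >= sf2@targetFit]
  if (length(reached)) {
    expect_identical(chosenPower(sf2), min(reached))
  } else {
    expect_identical(chosenPower(sf2),
                     sf2@table$power[which.max(sf2@table$fit)])
  }
})

test_that("edge-list export filters by weight and orders deterministically", {
  net <- defaultNetwork()
  el <- exportEdgeList(net, threshold = 0.3)
  expect_true(all(el$weight >= 0.3))
  expect_true(!is.unsorted(rev(el$weight)))
  df <- moduleAssignments(net)
  expect_identical(nrow(df), length(moduleLabels(net)))
  expect_true(all(c("transcript", "module", "kTotal", "kWithin") %in%
                    colnames(df)))
})
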