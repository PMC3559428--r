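# Composition descriptors, Pearson-correlation distances, neighbor
# joining, GC metrics, pI, COG outliers and genomic signatures.

test_that("amino-acid frequencies follow their definition", {
  f <- aaFrequency(c(g = "AAAA"))
  expect_equal(unname(f["A"]), 1)
  expect_equal(sum(f), 1)
  f2 <- aaFrequency(c(g = "ACACAC"))
  expect_equal(unname(f2[c("A", "C")]), c(0.5, 0.5))
  expect_error(aaFrequency(c(g = "AB")), "alphabet")
  expect_silent(aaFrequency(c(g = "AXA"), mode = "lenient"))
  # sampling convergence to the generating composition
  sim <- simulateOrthologProteomes(simulationConfig(
    nProteins = 400, lengthMean = 250, subRate = 0, seed = 17))
  f3 <- aaFrequency(sim$proteomeA)
  expect_lt(max(abs(f3 - standardAaFrequencies())), 0.01)
})

test_that("Pearson correlation distance has its invariances", {
  u <- c(0.5, 0.3, 0.2)
  expect_equal(pearsonCorrelationDistance(u, u), 0)
  expect_equal(pearsonCorrelationDistance(u, 3 * u + 1), 0)
  # frozen hand computation: r = -0.9286 for the reversed vector
  d <- pearsonCorrelationDistance(u, rev(u))
  expect_equal(d, 1.928571, tolerance = 1e-6)
  expect_error(pearsonCorrelationDistance(u, c(1, 1, 1)), "constant")
  expect_error(pearsonCorrelationDistance(u, c(1, 2)), "equal length")
  set.seed(1)
  v <- runif(20)
  w <- runif(20)
  expect_equal(pearsonCorrelationDistance(v, w),
               pearsonCorrelationDistance(2 + 5 * v, w))
})

test_that("three-taxon neighbor joining reproduces the closed form", {
  d <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  pend <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighborJoining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive five-taxon trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(99)
  ref <- randomAdditiveTree(5)
  tr <- neighborJoining(ref$d)
  expect_equal(phangorn::RF.dist(tr, ref$tree, check.labels = TRUE), 0)
  co <- ape::cophenetic.phylo(tr)[rownames(ref$d), colnames(ref$d)]
  expect_lt(max(abs(co - ref$d)), 1e-9)
})

test_that("NJ is deterministic under Q ties", {
  # ultrametric 4-taxon matrix with two identical Q minima
  d <- matrix(2, 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 1
  diag(d) <- 0
  t1 <- ape::write.tree(neighborJoining(d))
  t2 <- ape::write.tree(neighborJoining(d))
  expect_identical(t1, t2)
  expect_equal(phangorn::RF.dist(
    neighborJoining(d),
    ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:0.5,d:0.5);")), 0)
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    ref <- randomAdditiveTree(n)
    noisy <- ref$d + matrix(runif(n * n, 0, 0.02), n, n)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    mine <- neighborJoining(noisy)
    apes <- ape::nj(as.dist(noisy))
    expect_equal(phangorn::RF.dist(mine, apes, check.labels = TRUE), 0)
  }
})

test_that("negative NJ branch lengths are clamped, deficit moved to sister", {
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 8,
                9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighborJoining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("GC and GC3 follow their definitions", {
  expect_equal(unname(suppressWarnings(
    gcMetrics(c(x = "GCGC"), mode = "lenient"))["gc"]), 100)
  expect_equal(unname(gcMetrics(c(x = "ATGGCC"))["gc3"]), 100)
  expect_equal(unname(gcMetrics(c(x = "ATGAAA"))["gc3"]), 50)
  expect_error(gcMetrics(c(x = "ATGAA")), "divisible")
  expect_warning(g <- gcMetrics(c(x = "ATGAA", y = "ATGGGG"),
                                mode = "lenient"), "excluded")
  expect_equal(unname(g["gc3"]), 100)
  # terminal stop exclusion
  withStop <- c(x = "ATGGGGTAA")
  expect_equal(unname(gcMetrics(withStop)["gc3"]), 200 / 3,
               tolerance = 1e-9)
  expect_equal(unname(gcMetrics(withStop, excludeStop = TRUE)["gc3"]), 100)
})

test_that("isoelectric points respect the pKa chemistry", {
  # closed form for a peptide with no ionisable side chain
  expect_equal(isoelectricPoint("GG")[[1]], (8.6 + 3.6) / 2,
               tolerance = 1e-3)
  base <- isoelectricPoint("GGAVLGG")[[1]]
  expect_gte(isoelectricPoint("GGAVLGGK")[[1]], base)
  expect_lt(isoelectricPoint("DDDD")[[1]], isoelectricPoint("KKKK")[[1]])
  expect_error(isoelectricPoint(""), "non-empty")
  # loose agreement with the seqinr reference implementation
  skip_if_not_installed("seqinr")
  seqs <- c("MKVLAWTTAGDE", "DEDEDEKKRH", "ACDEFGHIKLMNPQRSTVWY")
  mine <- isoelectricPoint(seqs)
  ref <- vapply(seqs, function(s)
    seqinr::computePI(strsplit(s, "")[[1]]), numeric(1))
  expect_lt(max(abs(mine - ref)), 1.0)
})

test_that("COG outlier rule flags two-standard-deviation departures", {
  tab <- rbind(
    focal = c(17, 83),
    r1 = c(10, 90), r2 = c(12, 88), r3 = c(14, 86))
  colnames(tab) <- c("C", "rest")
  # reference proportions 0.10/0.12/0.14: mean 0.12, sd 0.02
  out <- cogOutliers(tab, "focal", c("r1", "r2", "r3"))
  expect_equal(out$flag[out$category == "C"], "high")
  tab2 <- tab
  tab2["focal", ] <- c(15, 85)
  expect_equal(cogOutliers(tab2, "focal",
                           c("r1", "r2", "r3"))$flag[1], "none")
  tab3 <- tab
  tab3["focal", ] <- c(7, 93)
  expect_equal(cogOutliers(tab3, "focal",
                           c("r1", "r2", "r3"))$flag[1], "low")
  # identical focal and references: nothing flagged
  same <- rbind(focal = c(10, 90), r1 = c(10, 90), r2 = c(10, 90),
                r3 = c(10, 90))
  colnames(same) <- c("C", "rest")
  expect_true(all(cogOutliers(same, "focal",
                              c("r1", "r2", "r3"))$flag == "none"))
  # zero-variance references with a deviating focal: flagged
  expect_equal(cogOutliers(rbind(focal = c(12, 88), same[-1, ]),
                           "focal", c("r1", "r2", "r3"))$flag[1], "high")
  expect_error(cogOutliers(tab, "focal", c("focal", "r1")), "must not")
  expect_error(cogOutliers(tab, "focal", "r1"), "at least two")
})

test_that("genomic signatures: tetranucleotides and RSCU", {
  g <- genomicSignatures(c(x = "AAAA"))
  expect_equal(unname(g$tetra["AAAA"]), 1)
  expect_equal(sum(g$tetra), 1)

  g2 <- genomicSignatures(c(x = "ATGATG"))
  expect_equal(g2$rscu$rscu[g2$rscu$codon == "ATG"], 1)

  # uniform synonymous usage within a family gives RSCU 1 for the family
  leu <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  g3 <- genomicSignatures(c(x = paste0(leu, collapse = "")))
  expect_equal(g3$rscu$rscu[g3$rscu$codon %in% leu], rep(1, 6))

  # cross-check RSCU against seqinr on a random CDS
  skip_if_not_installed("seqinr")
  cds <- as.character(simulateCdsSet(1, 200, 50, seed = 8))
  mine <- genomicSignatures(c(x = cds))$rscu
  ref <- seqinr::uco(strsplit(tolower(cds), "")[[1]], index = "rscu")
  refv <- ref[tolower(mine$codon)]
  keep <- !is.na(mine$rscu) & is.finite(refv)
  expect_lt(max(abs(mine$rscu[keep] - refv[keep])), 1e-8)
})

test_that("distinct simulated compositions separate into two NJ clades", {
  skip_if_not_installed("phangorn")
  set.seed(123)
  shift <- standardAaFrequencies()
  up <- c("A", "H", "R", "T")
  down <- c("D", "E", "K", "N", "S", "Y")
  shift[up] <- shift[up] * 1.4
  shift[down] <- shift[down] * 0.75
  shift <- shift / sum(shift)
  comps <- list()
  for (i in 1:4) {
    jitter1 <- standardAaFrequencies() * exp(rnorm(20, 0, 0.05))
    jitter2 <- shift * exp(rnorm(20, 0, 0.05))
    cfg1 <- simulationConfig(nProteins = 30, lengthMean = 200,
                             subRate = 0, seed = 1000 + i,
                             composition = jitter1 / sum(jitter1))
    cfg2 <- simulationConfig(nProteins = 30, lengthMean = 200,
                             subRate = 0, seed = 2000 + i,
                             composition = jitter2 / sum(jitter2))
    comps[[paste0("grp1_", i)]] <-
      aaFrequency(simulateOrthologProteomes(cfg1)$proteomeA)
    comps[[paste0("grp2_", i)]] <-
      aaFrequency(simulateOrthologProteomes(cfg2)$proteomeA)
  }
  tr <- neighborJoining(compositionDistanceMatrix(comps))
  expect_true(hasCleanSplit(tr, paste0("grp1_", 1:4)))
})
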