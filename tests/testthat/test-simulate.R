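# Synthetic-data generators: parameter validation, determinism,
# ground-truth bookkeeping and target recovery.

test_that("config validation rejects invalid rates, fractions and bias", {
  expect_error(simulationConfig(nProteins = 0), "nProteins")
  expect_error(simulationConfig(subRate = -0.1), "subRate")
  expect_error(simulationConfig(subRate = NaN), "subRate")
  expect_error(simulationConfig(paralogFraction = 1.2), "paralogFraction")
  expect_error(simulationConfig(biasPairs = c("K>R" = Inf)), "biasPairs")
  expect_error(simulationConfig(biasPairs = c("KR" = 2)), "biasPairs")
  expect_error(simulationConfig(biasPairs = c("K>K" = 2)), "biasPairs")
  expect_error(simulateSpotTable(10, planted = c(s1 = -2)), "planted")
  expect_error(simulateCdsSet(10, 50, targetGc3 = 120), "targetGc3")
})

test_that("zero-rate simulation returns identical proteomes and empty truth", {
  sim <- simulateOrthologProteomes(simulationConfig(
    nProteins = 10, lengthMean = 80, lengthSd = 5, subRate = 0,
    indelRate = 0, paralogFraction = 0, orphanFraction = 0, seed = 3))
  expect_identical(unname(as.character(sim$proteomeA)),
                   unname(as.character(sim$proteomeB)))
  expect_identical(nrow(sim$truth$events), 0L)
  offDiag <- sim$truth$directedCounts
  diag(offDiag) <- 0
  expect_true(all(offDiag == 0))
})

test_that("identical seeds reproduce byte-identical output, new seeds vary", {
  cfg <- simulationConfig(nProteins = 15, lengthMean = 100, subRate = 0.1,
                          indelRate = 0.01, seed = 11)
  s1 <- simulateOrthologProteomes(cfg)
  s2 <- simulateOrthologProteomes(cfg)
  expect_identical(as.character(s1$proteomeA), as.character(s2$proteomeA))
  expect_identical(as.character(s1$proteomeB), as.character(s2$proteomeB))
  expect_identical(s1$truth$events, s2$truth$events)
  cfg2 <- simulationConfig(nProteins = 15, lengthMean = 100, subRate = 0.1,
                           indelRate = 0.01, seed = 12)
  s3 <- simulateOrthologProteomes(cfg2)
  expect_false(identical(as.character(s1$proteomeA),
                         as.character(s3$proteomeA)))
})

test_that("directional bias shows up in the generator's own event log", {
  sim <- simulateOrthologProteomes(simulationConfig(
    nProteins = 50, lengthMean = 300, subRate = 0.1,
    biasPairs = c("K>R" = 2.0), seed = 42))
  ev <- sim$truth$events
  evB <- ev[ev$branch == "B", ]
  kr <- sum(evB$from == "K" & evB$to == "R")
  rk <- sum(evB$from == "R" & evB$to == "K")
  expect_gt(kr, rk)
  # and the directed state counts agree
  expect_gt(sim$truth$directedCounts["K", "R"],
            sim$truth$directedCounts["R", "K"])
})

test_that("substitution events match the Hamming difference at non-indel sites", {
  sim <- simulateOrthologProteomes(simulationConfig(
    nProteins = 20, lengthMean = 150, subRate = 0.15, indelRate = 0,
    seed = 5))
  a <- paste0(as.character(sim$proteomeA), collapse = "")
  b <- paste0(as.character(sim$proteomeB), collapse = "")
  hamming <- sum(utf8ToInt(a) != utf8ToInt(b))
  offDiag <- sim$truth$directedCounts
  diag(offDiag) <- 0
  expect_equal(hamming, sum(offDiag))
  # sites can be hit on both branches; the state count is what the
  # downstream analysis sees, so it is the conserved quantity here
  expect_lte(sum(offDiag), nrow(sim$truth$events))
})

test_that("replicate seeds give stable marginal divergence statistics", {
  idents <- vapply(1:20, function(s) {
    sim <- simulateOrthologProteomes(simulationConfig(
      nProteins = 10, lengthMean = 200, subRate = 0.2, seed = s))
    dc <- sim$truth$directedCounts
    sum(diag(dc)) / sum(dc)
  }, numeric(1))
  # replicates scatter tightly around a common mean: small spread, no
  # replicate far outside it
  expect_lt(sd(idents), 0.01)
  expect_true(all(abs(idents - mean(idents)) <= 3 * sd(idents) + 1e-9))
  # and close to the configured divergence: p_diff ~ subRate (two branches
  # of subRate/2, minus double hits)
  expect_lt(abs(mean(1 - idents) - 0.2), 0.02)
})

test_that("unbiased replicates have symmetric expected directed counts", {
  signed <- matrix(0, 50, 3)
  for (s in 1:50) {
    sim <- simulateOrthologProteomes(simulationConfig(
      nProteins = 10, lengthMean = 150, subRate = 0.2, seed = 100 + s))
    dc <- sim$truth$directedCounts
    signed[s, ] <- c(dc["K", "R"] - dc["R", "K"],
                     dc["A", "E"] - dc["E", "A"],
                     dc["L", "S"] - dc["S", "L"])
  }
  for (k in 1:3) {
    expect_lte(abs(mean(signed[, k])), 2 * sd(signed[, k]))
  }
})

test_that("paralogs and orphans are added with distinct ids", {
  sim <- simulateOrthologProteomes(simulationConfig(
    nProteins = 20, lengthMean = 100, subRate = 0.05,
    paralogFraction = 0.2, orphanFraction = 0.1, seed = 9))
  expect_length(sim$proteomeA, 20 + 2)          # orphans only
  expect_length(sim$proteomeB, 20 + 4 + 2)      # paralogs + orphans
  expect_true(all(grepl("p$", grep("^B\\d+p$", names(sim$proteomeB),
                                   value = TRUE))))
  # ortholog map ids all exist exactly once per proteome
  expect_true(all(sim$truth$orthologMap$id_a %in% names(sim$proteomeA)))
  expect_true(all(sim$truth$orthologMap$id_b %in% names(sim$proteomeB)))
})

test_that("CDS generator honours degenerate and intermediate GC3 targets", {
  thirdPos <- function(x) {
    vapply(as.character(x), function(s) {
      p3 <- substring(s, seq(3, nchar(s), 3), seq(3, nchar(s), 3))
      paste0(p3[-1L], collapse = "")   # non-start codons
    }, character(1))
  }
  hi <- simulateCdsSet(5, 40, targetGc3 = 100, seed = 2)
  expect_true(all(Biostrings::width(hi) %% 3 == 0))
  expect_true(all(substr(as.character(hi), 1, 3) == "ATG"))
  expect_true(all(grepl("^[GC]+$", thirdPos(hi))))
  lo <- simulateCdsSet(5, 40, targetGc3 = 0, seed = 2)
  expect_true(all(grepl("^[AT]+$", thirdPos(lo))))
  mid <- simulateCdsSet(200, 300, targetGc3 = 55, seed = 7)
  expect_lt(abs(unname(gcMetrics(mid)["gc3"]) - 55), 1)
})

test_that("spot generator plants exact ratios when noise-free", {
  st0 <- simulateSpotTable(20, noiseCv = 0, seed = 1)
  v <- reshape(st0[, c("spot_id", "condition", "volume")],
               idvar = "spot_id", timevar = "condition",
               direction = "wide")
  expect_equal(v[[2]] / v[[3]], rep(1, 20))
  st1 <- simulateSpotTable(20, planted = c(s1 = 3.0), noiseCv = 0, seed = 1)
  w <- st1[st1$spot_id == "s1", ]
  expect_equal(w$volume[w$condition == "high"] /
                 w$volume[w$condition == "low"], 3.0)
  expect_true(all(st1$volume > 0))
})

test_that("noisy planted ratios are recovered on average", {
  ratios <- vapply(1:100, function(s) {
    st <- simulateSpotTable(30, planted = c(s1 = 2.0), noiseCv = 0.1,
                            seed = s)
    w <- st[st$spot_id == "s1", ]
    w$volume[w$condition == "high"] / w$volume[w$condition == "low"]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2.0) / 2.0, 0.05)
})
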