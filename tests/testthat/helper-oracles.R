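# Independent oracles used across the suite. These never call the code
# paths they check.

# Brute-force global alignment optimum under affine gap penalties: every
# monotone alignment path is enumerated and scored from scratch (a gap of
# length L costs gapOpen + L * gapExtend). Feasible for short sequences.
bruteForceAlignScore <- function(a, b, subMat, gapOpen = 11, gapExtend = 1) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  m <- length(ca)
  n <- length(cb)
  best <- -Inf
  scorePath <- function(ops) {
    i <- 0L; j <- 0L; s <- 0; prev <- ""
    for (op in ops) {
      if (op == "M") {
        i <- i + 1L; j <- j + 1L
        s <- s + subMat[ca[i], cb[j]]
      } else if (op == "D") {      # gap in b
        i <- i + 1L
        s <- s - gapExtend - (if (prev != "D") gapOpen else 0)
      } else {                     # gap in a
        j <- j + 1L
        s <- s - gapExtend - (if (prev != "I") gapOpen else 0)
      }
      prev <- op
    }
    s
  }
  rec <- function(i, j, ops) {
    if (i == m && j == n) {
      sc <- scorePath(ops)
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i < m && j < n) rec(i + 1L, j + 1L, c(ops, "M"))
    if (i < m) rec(i + 1L, j, c(ops, "D"))
    if (j < n) rec(i, j + 1L, c(ops, "I"))
  }
  rec(0L, 0L, character(0))
  best
}

randomProteinSeq <- function(len) {
  paste0(sample(aaAlphabet(), len, replace = TRUE), collapse = "")
}

# Exact two-sided binomial p-value for a 50:50 split, via stats::binom.test.
exactBinomialP <- function(x, y) {
  if (x + y == 0) return(1)
  stats::binom.test(x, x + y, p = 0.5)$p.value
}

# Mid-p variant of the exact two-sided binomial: half the point mass of
# the observed outcome is counted. The standard calibration when
# comparing a discrete exact test against an asymptotic statistic.
midPBinomialP <- function(x, y) {
  n <- x + y
  if (n == 0) return(1)
  lo <- min(x, y)
  min(1, 2 * (stats::pbinom(lo, n, 0.5) - 0.5 * stats::dbinom(lo, n, 0.5)))
}

# Random additive tree and its exact leaf-to-leaf distance matrix.
randomAdditiveTree <- function(nTaxa) {
  tr <- ape::rtree(nTaxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Whether an unrooted tree contains the bipartition separating `group`
# from the remaining tips.
hasCleanSplit <- function(tree, group) {
  other <- setdiff(tree$tip.label, group)
  rooted <- ape::root(tree, outgroup = other[1L], resolve.root = TRUE)
  ape::is.monophyletic(rooted, group)
}

# Expected DA results computed independently from a long spot table,
# mirroring per-gel total normalisation and replicate averaging.
naiveDaOracle <- function(table, threshold = 1.5) {
  conds <- unique(table$condition)
  rel <- list()
  for (cc in conds) {
    sub <- table[table$condition == cc, ]
    perRep <- lapply(split(sub, sub$replicate), function(g) {
      stats::setNames(g$volume / sum(g$volume), g$spot_id)
    })
    ids <- unique(sub$spot_id)
    rel[[cc]] <- sapply(ids, function(id)
      mean(sapply(perRep, function(v) v[[id]])))
  }
  ids <- unique(table$spot_id)
  out <- data.frame(spot_id = ids, stringsAsFactors = FALSE)
  r1 <- rel[[conds[1L]]][ids]
  r2 <- rel[[conds[2L]]][ids]
  out$da <- pmax(r1, r2) / pmin(r1, r2)
  out$significant <- out$da >= threshold
  out
}
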