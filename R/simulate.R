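# Synthetic data generators: ortholog proteome pairs diverged under a
# controllable, optionally direction-biased substitution process; CDS sets
# with a target GC3; two-condition spot-volume tables with planted fold
# changes. Every generator records its ground truth so downstream stages
# have a parameter-recovery test surface.

#' Configuration for the ortholog proteome simulator
#'
#' @param nProteins number of ortholog pairs to simulate.
#' @param lengthMean,lengthSd protein length distribution (residues);
#'   lengths are drawn from a normal and clamped at 30.
#' @param subRate expected fraction of sites substituted between the two
#'   descendants (per-site probability, split evenly over the two
#'   branches). Must lie in \[0, 1\].
#' @param biasPairs named numeric vector of directional multipliers for
#'   ordered residue pairs, names of the form `"K>R"`. The multiplier
#'   scales the exchange weight of that ordered substitution on the branch
#'   leading to proteome B, creating a directional excess of a-to-b counts
#'   when the matrix is read with A as the reference.
#' @param indelRate per-site probability of a single-residue indel on each
#'   descendant branch (half deletions, half insertions).
#' @param paralogFraction fraction of genes duplicated in proteome B as
#'   diverged paralogs (three times the substitution rate), to exercise
#'   best-hit tie handling.
#' @param orphanFraction fraction of additional unpaired genes added to
#'   each proteome.
#' @param seed integer seed governing all randomness.
#' @param composition ancestral residue frequencies (named, ordered as
#'   [aaAlphabet()]); defaults to [standardAaFrequencies()].
#' @param exchangeWeights optional symmetric 20x20 non-negative matrix of
#'   base exchange weights (diagonal ignored); default uniform. The
#'   symmetric base process is multiplied by `biasPairs` on branch B.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nProteins = 100L, lengthMean = 300, lengthSd = 60,
                             subRate = 0.2, biasPairs = NULL, indelRate = 0,
                             paralogFraction = 0, orphanFraction = 0,
                             seed = 1L,
                             composition = standardAaFrequencies(),
                             exchangeWeights = NULL) {
  nProteins <- .assertCount(nProteins, "nProteins")
  .assertNonNeg(lengthMean, "lengthMean")
  .assertNonNeg(lengthSd, "lengthSd")
  .assertFraction(subRate, "subRate")
  .assertFraction(indelRate, "indelRate")
  .assertFraction(paralogFraction, "paralogFraction")
  .assertFraction(orphanFraction, "orphanFraction")
  seed <- .assertCount(seed, "seed", min = 0L)
  aa <- aaAlphabet()
  if (!is.numeric(composition) || length(composition) != 20L ||
      any(!is.finite(composition)) || any(composition < 0) ||
      sum(composition) <= 0)
    stop("'composition' must be 20 non-negative frequencies", call. = FALSE)
  composition <- composition / sum(composition)
  names(composition) <- aa
  if (is.null(exchangeWeights)) {
    exchangeWeights <- matrix(1, 20L, 20L, dimnames = list(aa, aa))
  } else {
    exchangeWeights <- as.matrix(exchangeWeights)
    if (!identical(dim(exchangeWeights), c(20L, 20L)) ||
        any(!is.finite(exchangeWeights)) || any(exchangeWeights < 0) ||
        !isTRUE(all.equal(exchangeWeights, t(exchangeWeights))))
      stop("'exchangeWeights' must be a symmetric non-negative 20x20 matrix",
           call. = FALSE)
    dimnames(exchangeWeights) <- list(aa, aa)
  }
  if (!is.null(biasPairs)) {
    if (!is.numeric(biasPairs) || is.null(names(biasPairs)) ||
        any(!is.finite(biasPairs)) || any(biasPairs <= 0))
      stop("'biasPairs' must be a named numeric vector of finite positive multipliers",
           call. = FALSE)
    parts <- strsplit(names(biasPairs), ">", fixed = TRUE)
    ok <- vapply(parts, function(p) length(p) == 2L && all(p %in% aa) &&
                   p[1L] != p[2L], logical(1L))
    if (!all(ok))
      stop("'biasPairs' names must look like \"K>R\" with two distinct residues",
           call. = FALSE)
  }
  structure(list(nProteins = nProteins, lengthMean = lengthMean,
                 lengthSd = lengthSd, subRate = subRate,
                 biasPairs = biasPairs, indelRate = indelRate,
                 paralogFraction = paralogFraction,
                 orphanFraction = orphanFraction, seed = seed,
                 composition = composition,
                 exchangeWeights = exchangeWeights),
            class = "SimulationConfig")
}

# Substitute sites of the coded ancestor with per-site probability p,
# drawing targets from the (possibly direction-biased) weight matrix W.
.applyBranch <- function(anc, p, W) {
  hit <- which(stats::runif(length(anc)) < p)
  from <- anc[hit]
  to <- integer(length(hit))
  for (a in seq_len(20L)) {
    sel <- which(from == a)
    if (length(sel)) {
      w <- W[a, ]
      w[a] <- 0
      to[sel] <- sample.int(20L, length(sel), replace = TRUE, prob = w)
    }
  }
  res <- anc
  res[hit] <- to
  list(seq = res, hit = hit, from = from, to = to)
}

# Single-residue indels: each site is deleted with probability p/2 and
# followed by an inserted residue with probability p/2.
.applyIndels <- function(codes, prot, pos, p, comp) {
  if (p <= 0)
    return(list(codes = codes, prot = prot, pos = pos,
                delAt = integer(0), insAfter = integer(0)))
  L <- length(codes)
  del <- stats::runif(L) < p / 2
  ins <- stats::runif(L) < p / 2
  keyO <- which(!del)
  keyI <- which(ins)
  insCodes <- sample.int(20L, length(keyI), replace = TRUE, prob = comp)
  allKey <- c(keyO, keyI + 0.5)
  allCodes <- c(codes[keyO], insCodes)
  allProt <- c(prot[keyO], prot[keyI])
  allPos <- c(pos[keyO], rep(NA_integer_, length(keyI)))
  o <- order(allKey)
  list(codes = allCodes[o], prot = allProt[o], pos = allPos[o],
       delAt = which(del), insAfter = keyI)
}

# Split a coded residue vector into per-protein strings.
.codesToStrings <- function(codes, prot, nProt) {
  full <- .codesToSeq(codes)
  lens <- tabulate(prot, nbins = nProt)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  substring(full, starts, ends)
}

#' Simulate a pair of ortholog proteomes with known ground truth
#'
#' Ancestral proteins are drawn from the configured residue composition;
#' each descendant branch substitutes sites independently (single hit per
#' site) under a symmetric base exchange process, multiplied by the
#' configured directional bias on the branch leading to proteome B.
#' Optional single-residue indels, diverged paralog duplicates and
#' unpaired orphan genes complete the pair.
#'
#' @param config a [simulationConfig()].
#' @return A list with elements `proteomeA`, `proteomeB`
#'   ([Biostrings::AAStringSet]) and `truth`, a list holding
#'   `orthologMap` (data.frame `id_a`, `id_b`), `events` (one row per
#'   substitution: `pair_id`, `branch`, `position`, `from`, `to`),
#'   `directedCounts` (20x20 state-count matrix over non-indel sites,
#'   rows = proteome A state) and `indels`.
#' @export
simulateOrthologProteomes <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simulationConfig, as.list(config))
  set.seed(config$seed)
  n <- config$nProteins
  aa <- aaAlphabet()
  lens <- pmax(30L, as.integer(round(stats::rnorm(n, config$lengthMean,
                                                  config$lengthSd))))
  L <- sum(lens)
  prot <- rep.int(seq_len(n), lens)
  pos <- sequence(lens)
  anc <- sample.int(20L, L, replace = TRUE, prob = config$composition)

  WA <- config$exchangeWeights
  WB <- config$exchangeWeights
  if (!is.null(config$biasPairs)) {
    parts <- strsplit(names(config$biasPairs), ">", fixed = TRUE)
    for (i in seq_along(parts)) {
      a <- match(parts[[i]][1L], aa)
      b <- match(parts[[i]][2L], aa)
      WB[a, b] <- WB[a, b] * config$biasPairs[[i]]
    }
  }
  p <- config$subRate / 2
  brA <- .applyBranch(anc, p, WA)
  brB <- .applyBranch(anc, p, WB)

  idsA <- sprintf("A%04d", seq_len(n))
  idsB <- sprintf("B%04d", seq_len(n))
  pairIds <- sprintf("pair%04d", seq_len(n))

  branchEvents <- function(br, label) {
    data.frame(pair_id = pairIds[prot[br$hit]],
               branch = rep(label, length(br$hit)),
               position = pos[br$hit], from = aa[br$from],
               to = aa[br$to], stringsAsFactors = FALSE)
  }
  events <- rbind(branchEvents(brA, "A"), branchEvents(brB, "B"))

  # Directed state counts over non-indel sites: rows = A state, cols = B.
  directedCounts <- matrix(
    tabulate((brA$seq - 1L) * 20L + brB$seq, nbins = 400L),
    nrow = 20L, byrow = TRUE, dimnames = list(aa, aa))

  indA <- .applyIndels(brA$seq, prot, pos, config$indelRate,
                       config$composition)
  indB <- .applyIndels(brB$seq, prot, pos, config$indelRate,
                       config$composition)
  indels <- rbind(
    if (length(indA$delAt) || length(indA$insAfter))
      data.frame(pair_id = pairIds[prot[c(indA$delAt, indA$insAfter)]],
                 branch = "A",
                 position = pos[c(indA$delAt, indA$insAfter)],
                 type = rep(c("del", "ins"),
                            c(length(indA$delAt), length(indA$insAfter))),
                 stringsAsFactors = FALSE),
    if (length(indB$delAt) || length(indB$insAfter))
      data.frame(pair_id = pairIds[prot[c(indB$delAt, indB$insAfter)]],
                 branch = "B",
                 position = pos[c(indB$delAt, indB$insAfter)],
                 type = rep(c("del", "ins"),
                            c(length(indB$delAt), length(indB$insAfter))),
                 stringsAsFactors = FALSE))
  if (is.null(indels))
    indels <- data.frame(pair_id = character(0), branch = character(0),
                         position = integer(0), type = character(0))

  seqsA <- .codesToStrings(indA$codes, indA$prot, n)
  seqsB <- .codesToStrings(indB$codes, indB$prot, n)
  names(seqsA) <- idsA
  names(seqsB) <- idsB

  # Paralogs: diverged duplicates of proteome-B genes.
  nPar <- round(config$paralogFraction * n)
  if (nPar > 0L) {
    parGenes <- sort(sample.int(n, nPar))
    parSeqs <- character(nPar)
    for (k in seq_len(nPar)) {
      g <- parGenes[k]
      codes <- .seqToCodes(seqsB[g])
      extra <- .applyBranch(codes, min(1, 3 * config$subRate), WB)
      parSeqs[k] <- .codesToSeq(extra$seq)
    }
    names(parSeqs) <- sprintf("B%04dp", parGenes)
    seqsB <- c(seqsB, parSeqs)
  }

  # Orphans: unpaired genes drawn fresh from the ancestral composition.
  nOrph <- round(config$orphanFraction * n)
  if (nOrph > 0L) {
    for (side in c("A", "B")) {
      oLens <- pmax(30L, as.integer(round(stats::rnorm(nOrph,
                config$lengthMean, config$lengthSd))))
      oProt <- rep.int(seq_len(nOrph), oLens)
      oCodes <- sample.int(20L, sum(oLens), replace = TRUE,
                           prob = config$composition)
      oSeqs <- .codesToStrings(oCodes, oProt, nOrph)
      names(oSeqs) <- sprintf("%sX%03d", side, seq_len(nOrph))
      if (side == "A") seqsA <- c(seqsA, oSeqs) else seqsB <- c(seqsB, oSeqs)
    }
  }

  list(proteomeA = Biostrings::AAStringSet(seqsA),
       proteomeB = Biostrings::AAStringSet(seqsB),
       truth = list(
         orthologMap = data.frame(id_a = idsA, id_b = idsB,
                                  pair_id = pairIds,
                                  stringsAsFactors = FALSE),
         events = events,
         directedCounts = directedCounts,
         indels = indels,
         config = config))
}

#' Simulate coding sequences with a target third-position GC content
#'
#' Every sequence starts with ATG; all later codons draw their first two
#' positions uniformly and their third position G/C with probability
#' `targetGc3/100` (A/T otherwise), so the set's GC3 converges to the
#' target as the number of codons grows. The invariant start codon
#' contributes one fixed G per sequence, a vanishing perturbation.
#'
#' @param n number of sequences.
#' @param lengthCodons codons per sequence (>= 2, including the start).
#' @param targetGc3 target GC3 percentage in \[0, 100\].
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet].
#' @export
simulateCdsSet <- function(n, lengthCodons, targetGc3, seed = 1L) {
  n <- .assertCount(n, "n")
  lengthCodons <- .assertCount(lengthCodons, "lengthCodons", min = 2L)
  .assertPercent(targetGc3, "targetGc3")
  seed <- .assertCount(seed, "seed", min = 0L)
  set.seed(seed)
  t <- targetGc3 / 100
  m <- n * (lengthCodons - 1L)  # non-start codons
  p12 <- sample(c("A", "C", "G", "T"), 2L * m, replace = TRUE)
  p3 <- sample(c("G", "C", "A", "T"), m, replace = TRUE,
               prob = c(t / 2, t / 2, (1 - t) / 2, (1 - t) / 2))
  codonStr <- paste0(p12[seq_len(m)], p12[m + seq_len(m)], p3)
  perSeq <- matrix(codonStr, nrow = lengthCodons - 1L)
  seqs <- paste0("ATG", vapply(seq_len(n), function(j)
    paste0(perSeq[, j], collapse = ""), character(1L)))
  names(seqs) <- sprintf("cds%04d", seq_len(n))
  Biostrings::DNAStringSet(seqs)
}

#' Simulate a two-condition spot-volume table with planted fold changes
#'
#' Base volumes are drawn once per spot (log-normal) and shared by both
#' conditions; planted spots have their second-condition volume multiplied
#' by the stated fold change; multiplicative log-normal noise with the
#' stated coefficient of variation (mean-corrected, so expected volumes
#' equal the noise-free values) is then applied per measurement.
#'
#' @param nSpots number of spots; ids are `s1 ... sN`.
#' @param planted named numeric vector of fold changes (> 0) applied to
#'   the second condition, names matching spot ids.
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param nReplicates gels per condition.
#' @param seed integer seed.
#' @param conditions length-2 character vector of condition labels.
#' @return Long-format data.frame: `spot_id`, `condition`, `replicate`,
#'   `volume` (strictly positive).
#' @export
simulateSpotTable <- function(nSpots, planted = NULL, noiseCv = 0,
                              nReplicates = 1L, seed = 1L,
                              conditions = c("low", "high")) {
  nSpots <- .assertCount(nSpots, "nSpots")
  nReplicates <- .assertCount(nReplicates, "nReplicates")
  .assertNonNeg(noiseCv, "noiseCv")
  seed <- .assertCount(seed, "seed", min = 0L)
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stop("'conditions' must be two distinct labels", call. = FALSE)
  ids <- paste0("s", seq_len(nSpots))
  fold <- rep(1, nSpots)
  names(fold) <- ids
  if (!is.null(planted)) {
    if (!is.numeric(planted) || is.null(names(planted)) ||
        any(!is.finite(planted)) || any(planted <= 0))
      stop("'planted' must be a named numeric vector of positive fold changes",
           call. = FALSE)
    unknown <- setdiff(names(planted), ids)
    if (length(unknown))
      stop("unknown spot ids in 'planted': ", paste(unknown, collapse = ", "),
           call. = FALSE)
    fold[names(planted)] <- planted
  }
  set.seed(seed)
  base <- stats::rlnorm(nSpots, meanlog = log(1000), sdlog = 0.8)
  sdlog <- sqrt(log(1 + noiseCv^2))
  out <- expand.grid(spot_id = ids, condition = conditions,
                     replicate = seq_len(nReplicates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- base[match(out$spot_id, ids)] *
    ifelse(out$condition == conditions[2L], fold[match(out$spot_id, ids)], 1)
  noise <- if (noiseCv > 0)
    stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  else rep(1, nrow(out))
  out$volume <- mu * noise
  out[order(match(out$condition, conditions), out$replicate,
            match(out$spot_id, ids)), , drop = FALSE]
}
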