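# All-vs-all protein comparison, reciprocal-best-hit ortholog calling with
# coverage/identity thresholds, and global pairwise alignment of each
# ortholog pair. Alignment itself is delegated to Biostrings (Needleman-
# Wunsch with affine gaps); this module owns the scoring contract, the
# RBH semantics and the identity/coverage statistics.

#' Scoring scheme for protein global alignment
#'
#' @param matrix symmetric integer substitution score matrix over the 20
#'   canonical residues (rows/columns named); defaults to BLOSUM62.
#' @param gapOpen,gapExtend non-negative gap penalties; a gap of length L
#'   costs `gapOpen + L * gapExtend` (the BLASTP convention; defaults 11/1).
#' @return A list of class `ScoringScheme`.
#' @export
scoringScheme <- function(matrix = NULL, gapOpen = 11, gapExtend = 1) {
  .assertNonNeg(gapOpen, "gapOpen")
  .assertNonNeg(gapExtend, "gapExtend")
  if (is.null(matrix)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    matrix <- get("BLOSUM62", envir = environment())
  }
  aa <- aaAlphabet()
  if (!all(aa %in% rownames(matrix)) || !all(aa %in% colnames(matrix)))
    stop("substitution matrix must cover the 20 canonical residues",
         call. = FALSE)
  m <- matrix[aa, aa]
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  structure(list(matrix = m, gapOpen = gapOpen, gapExtend = gapExtend),
            class = "ScoringScheme")
}

#' @rdname scoringScheme
#' @export
defaultScoring <- function() scoringScheme()

# Substitution matrix extended with X scored 0 against everything,
# for lenient mode.
.scoringMatrix <- function(scoring, mode) {
  m <- scoring$matrix
  if (mode == "lenient") {
    m <- rbind(cbind(m, X = 0), X = 0)
    colnames(m)[21L] <- "X"
    rownames(m)[21L] <- "X"
  }
  m
}

.checkAlphabet <- function(seqs, mode) {
  allowed <- paste0(aaAlphabet(), collapse = "")
  if (mode == "lenient") allowed <- paste0(allowed, "X")
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad))
    stop("sequence contains letters outside the ",
         if (mode == "strict") "20-letter alphabet" else "alphabet plus X",
         ": ", paste(utils::head(names(seqs)[bad], 3L), collapse = ", "),
         call. = FALSE)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment under affine gap penalties, scored by
#' the given scheme. In lenient mode the letter X is accepted and scored 0
#' against everything; its columns are excluded from downstream
#' substitution counting.
#'
#' @param seqA,seqB protein sequences (character or AAString); non-empty.
#' @param scoring a [scoringScheme()].
#' @param mode `"strict"` (20-letter alphabet only) or `"lenient"`
#'   (X allowed).
#' @param idA,idB sequence identifiers stored on the result.
#' @return An [AlignedPair-class] object.
#' @export
globalAlign <- function(seqA, seqB, scoring = defaultScoring(),
                        mode = c("strict", "lenient"),
                        idA = "seq_a", idB = "seq_b") {
  mode <- match.arg(mode)
  seqA <- as.character(seqA)
  seqB <- as.character(seqB)
  if (nchar(seqA) == 0L || nchar(seqB) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  seqs <- c(a = seqA, b = seqB)
  .checkAlphabet(seqs, mode)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = .scoringMatrix(scoring, mode),
    gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend,
    type = "global")
  methods::new("AlignedPair", idA = idA, idB = idB,
               alnA = as.character(Biostrings::alignedPattern(pa)),
               alnB = as.character(Biostrings::alignedSubject(pa)),
               score = Biostrings::score(pa))
}

# Vectorized identity/coverage statistics from gapped sequence strings.
# Ungapped columns are those free of the gap character in both rows; the
# ambiguity letter X occupies a column (and so enters the identity
# denominator) but never counts as identical.
.alnStats <- function(alnA, alnB, lenA, lenB) {
  n <- length(alnA)
  nUngapped <- integer(n)
  nIdentical <- integer(n)
  resA <- integer(n)
  resB <- integer(n)
  gap <- utf8ToInt("-")
  for (i in seq_len(n)) {
    ca <- utf8ToInt(alnA[i])
    cb <- utf8ToInt(alnB[i])
    keep <- ca != gap & cb != gap
    a <- .aaIndex[ca]
    b <- .aaIndex[cb]
    nUngapped[i] <- sum(keep)
    nIdentical[i] <- sum(keep & !is.na(a) & !is.na(b) & a == b,
                         na.rm = TRUE)
    resA[i] <- sum(ca != gap)
    resB[i] <- sum(cb != gap)
  }
  list(n_ungapped = nUngapped, n_identical = nIdentical,
       identity = ifelse(nUngapped > 0, 100 * nIdentical / nUngapped,
                         NA_real_),
       coverage_a = 100 * resA / lenA, coverage_b = 100 * resB / lenB)
}

#' Identity and coverage of an aligned pair
#'
#' Identity is `100 * n_identical / n_ungapped_columns` (denominator:
#' columns with no gap and no ambiguity letter in either row); coverage of
#' each sequence is the percentage of its residues present in the
#' alignment. For a global alignment coverage is 100 by construction, but
#' the definitions hold for any alignment.
#'
#' @param pair an [AlignedPair-class].
#' @param lenA,lenB full (unaligned) sequence lengths; default the number
#'   of non-gap characters in each aligned row.
#' @return Named numeric: `identity`, `coverage_a`, `coverage_b`.
#'   Identity is `NA` (with a warning) when no ungapped column exists.
#' @export
identityCoverage <- function(pair, lenA = NULL, lenB = NULL) {
  stopifnot(methods::is(pair, "AlignedPair"))
  resA <- nchar(gsub("-", "", pair@alnA, fixed = TRUE))
  resB <- nchar(gsub("-", "", pair@alnB, fixed = TRUE))
  if (is.null(lenA)) lenA <- resA
  if (is.null(lenB)) lenB <- resB
  st <- .alnStats(pair@alnA, pair@alnB, lenA, lenB)
  if (st$n_ungapped == 0L)
    warning("alignment has no ungapped column; identity is undefined")
  c(identity = st$identity, coverage_a = st$coverage_a,
    coverage_b = st$coverage_b)
}

.makeOrthologSet <- function(id_a, id_b, aln_a, aln_b, score, lenA, lenB,
                             organisms) {
  st <- .alnStats(aln_a, aln_b, lenA, lenB)
  pairs <- S4Vectors::DataFrame(
    id_a = id_a, id_b = id_b, aln_a = aln_a, aln_b = aln_b, score = score,
    n_ungapped = st$n_ungapped, n_identical = st$n_identical,
    identity = st$identity, coverage_a = st$coverage_a,
    coverage_b = st$coverage_b)
  methods::new("OrthologSet", pairs = pairs, organisms = organisms)
}

#' Reciprocal-best-hit ortholog detection between two proteomes
#'
#' Scores every sequence of proteome A against every sequence of proteome
#' B by exact global alignment, then retains gene pairs `(gA, gB)` in
#' which each is the unique top-scoring hit of the other. Retained pairs
#' must additionally pass `identity >= minIdentity` and
#' `coverage >= minCoverage` on both sequences. Equal-score best hits make
#' the best hit non-unique and exclude the gene (strict uniqueness).
#'
#' @param proteomeA,proteomeB named [Biostrings::AAStringSet] (or named
#'   character vectors); non-empty.
#' @param scoring a [scoringScheme()].
#' @param minIdentity,minCoverage percent thresholds in \[0, 100\];
#'   defaults 30 and 70. Coverage is required of both sequences.
#' @param scoreFloor optional raw-score floor: alignments scoring below it
#'   are not considered hits.
#' @param mode `"strict"` or `"lenient"` (see [globalAlign()]).
#' @param organisms labels of the two organisms.
#' @return An [OrthologSet-class].
#' @export
reciprocalBestHits <- function(proteomeA, proteomeB,
                               scoring = defaultScoring(),
                               minIdentity = 30, minCoverage = 70,
                               scoreFloor = NULL,
                               mode = c("strict", "lenient"),
                               organisms = c("organism_A", "organism_B")) {
  mode <- match.arg(mode)
  .assertPercent(minIdentity, "minIdentity")
  .assertPercent(minCoverage, "minCoverage")
  a <- .asSequenceVector(proteomeA, "proteomeA")
  b <- .asSequenceVector(proteomeB, "proteomeB")
  .checkAlphabet(a, mode)
  .checkAlphabet(b, mode)
  subMat <- .scoringMatrix(scoring, mode)
  aSet <- Biostrings::AAStringSet(a)
  S <- matrix(NA_real_, nrow = length(a), ncol = length(b),
              dimnames = list(names(a), names(b)))
  for (j in seq_along(b)) {
    S[, j] <- Biostrings::pairwiseAlignment(
      aSet, Biostrings::AAString(b[[j]]), substitutionMatrix = subMat,
      gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend,
      type = "global", scoreOnly = TRUE)
  }
  if (!is.null(scoreFloor)) S[S < scoreFloor] <- -Inf

  # Unique best hit per gene, in each direction.
  bestOf <- function(scores) {
    m <- max(scores)
    if (!is.finite(m)) return(NA_integer_)
    w <- which(scores == m)
    if (length(w) == 1L) w else NA_integer_  # ties disqualify
  }
  bestB <- apply(S, 1L, bestOf)
  bestA <- apply(S, 2L, bestOf)
  iA <- which(!is.na(bestB))
  recip <- iA[!is.na(bestA[bestB[iA]]) & bestA[bestB[iA]] == iA]

  if (length(recip) == 0L) {
    return(.makeOrthologSet(character(0), character(0), character(0),
                            character(0), numeric(0), numeric(0), numeric(0),
                            organisms))
  }
  jB <- bestB[recip]
  alnA <- character(length(recip))
  alnB <- character(length(recip))
  for (k in seq_along(recip)) {
    pr <- globalAlign(a[[recip[k]]], b[[jB[k]]], scoring = scoring,
                      mode = mode, idA = names(a)[recip[k]],
                      idB = names(b)[jB[k]])
    alnA[k] <- pr@alnA
    alnB[k] <- pr@alnB
  }
  os <- .makeOrthologSet(names(a)[recip], names(b)[jB], alnA, alnB,
                         score = S[cbind(recip, jB)],
                         lenA = nchar(a[recip]), lenB = nchar(b[jB]),
                         organisms = organisms)
  keep <- !is.na(os@pairs$identity) &
    os@pairs$identity >= minIdentity &
    os@pairs$coverage_a >= minCoverage &
    os@pairs$coverage_b >= minCoverage
  methods::initialize(os, pairs = os@pairs[keep, , drop = FALSE])
}

#' Ortholog set from a simulation's ground-truth map
#'
#' Builds an [OrthologSet-class] directly from the true ortholog map of
#' [simulateOrthologProteomes()], bypassing the reciprocal-best-hit
#' search. Pairs of equal length simulated without indels are already
#' positionally aligned and are used as-is; unequal-length pairs are
#' globally aligned.
#'
#' @param sim result of [simulateOrthologProteomes()].
#' @param scoring a [scoringScheme()] (used only when alignment is
#'   needed).
#' @return An [OrthologSet-class].
#' @export
orthologSetFromSimulation <- function(sim, scoring = defaultScoring()) {
  a <- as.character(sim$proteomeA)
  b <- as.character(sim$proteomeB)
  map <- sim$truth$orthologMap
  sa <- a[map$id_a]
  sb <- b[map$id_b]
  alnA <- sa
  alnB <- sb
  needAln <- if (sim$truth$config$indelRate > 0) seq_along(sa)
             else which(nchar(sa) != nchar(sb))
  for (k in needAln) {
    pr <- globalAlign(sa[[k]], sb[[k]], scoring = scoring,
                      idA = map$id_a[k], idB = map$id_b[k])
    alnA[k] <- pr@alnA
    alnB[k] <- pr@alnB
  }
  .makeOrthologSet(map$id_a, map$id_b, unname(alnA), unname(alnB),
                   score = rep(NA_real_, nrow(map)),
                   lenA = nchar(sa), lenB = nchar(sb),
                   organisms = c("organism_A", "organism_B"))
}
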