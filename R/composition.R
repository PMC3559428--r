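# Composition descriptors (amino-acid frequencies, GC, GC3, isoelectric
# point, tetranucleotide and codon-usage signatures), Pearson-correlation
# distances, neighbor-joining tree construction and the COG-category
# two-standard-deviation outlier rule.

#' Amino-acid frequency vector of a proteome
#'
#' Frequency of each canonical residue over all residues of all
#' sequences. In strict mode non-canonical letters are an error; in
#' lenient mode they are ignored.
#'
#' @param proteome an [Biostrings::AAStringSet] or named character vector.
#' @param mode `"strict"` or `"lenient"`.
#' @return Named numeric vector of length 20 summing to 1, ordered as
#'   [aaAlphabet()].
#' @export
aaFrequency <- function(proteome, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  seqs <- .asSequenceVector(proteome)
  if (mode == "strict") .checkAlphabet(seqs, "strict")
  codes <- .aaIndex[utf8ToInt(paste0(seqs, collapse = ""))]
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L)
    stop("proteome contains no canonical residues", call. = FALSE)
  freq <- tabulate(codes, nbins = 20L) / length(codes)
  names(freq) <- aaAlphabet()
  freq
}

#' Pearson correlation distance between two composition vectors
#'
#' `d = 1 - r`, the complement of the Pearson correlation, in \[0, 2\].
#'
#' @param u,v numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return A single distance.
#' @export
pearsonCorrelationDistance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 3L)
    stop("'u' and 'v' must have equal length >= 3", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("correlation is undefined for a constant vector", call. = FALSE)
  1 - stats::cor(u, v)
}

#' Pairwise Pearson-correlation distance matrix
#'
#' @param comps matrix with one composition vector per row (rownames are
#'   organism labels), or a named list of equal-length vectors.
#' @return Symmetric distance matrix with zero diagonal, labels preserved
#'   in input order.
#' @export
compositionDistanceMatrix <- function(comps) {
  if (is.list(comps)) comps <- do.call(rbind, comps)
  comps <- as.matrix(comps)
  n <- nrow(comps)
  if (n < 2L) stop("need at least two composition vectors", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(comps), rownames(comps)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- pearsonCorrelationDistance(comps[i, ],
                                                       comps[j, ])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration using the Studier-Keppler Q
#' criterion. Ties in Q are broken by the lowest pair of current label
#' indices, making the join order deterministic. Negative branch lengths
#' are clamped to zero with the deficit transferred to the sister branch.
#'
#' @param d symmetric numeric matrix with zero diagonal and at least 3
#'   labelled taxa (or a `dist` object).
#' @return An unrooted `phylo` tree (ape) with branch lengths in the
#'   distance units of `d`.
#' @export
neighborJoining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (any(d < 0) || any(abs(diag(d)) > 1e-12) ||
      !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("'d' must be symmetric, non-negative, with zero diagonal",
         call. = FALSE)
  tips <- rownames(d)
  active <- seq_len(n)          # node ids of the active clusters
  D <- d
  nextNode <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)

  while (length(active) > 2L) {
    r <- length(active)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]
    j <- hit[1L, 2L]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    u <- nextNode
    nextNode <- nextNode + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lens <- c(lens, vi, vj)
    newD <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    active <- c(active[keep], u)
  }
  edges <- rbind(edges, c(active[2L], active[1L]))
  lens <- c(lens, max(0, D[1L, 2L]))

  # Orient edges away from the last internal node to build the phylo.
  nNode <- nextNode - 1L - n
  root <- nextNode - 1L
  adj <- vector("list", nextNode - 1L)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, lens[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, lens[k]))
  }
  # Renumber internal nodes in BFS order so the root becomes n + 1,
  # the numbering ape's tree utilities expect.
  outE <- matrix(0L, 0L, 2L)
  outL <- numeric(0)
  newId <- integer(nextNode - 1L)
  newId[seq_len(n)] <- seq_len(n)
  newId[root] <- n + 1L
  nextInternal <- n + 2L
  queue <- root
  seen <- logical(nextNode - 1L)
  seen[root] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[v]]
    for (k in seq_len(NROW(nb))) {
      w <- as.integer(nb[k, 1L])
      if (!seen[w]) {
        seen[w] <- TRUE
        if (w > n) {
          newId[w] <- nextInternal
          nextInternal <- nextInternal + 1L
        }
        outE <- rbind(outE, c(newId[v], newId[w]))
        outL <- c(outL, nb[k, 2L])
        queue <- c(queue, w)
      }
    }
  }
  tree <- list(edge = outE, edge.length = outL, tip.label = tips,
               Nnode = nNode)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' GC and third-codon-position GC content of a CDS set
#'
#' GC is computed over all A/C/G/T positions of all sequences; GC3 over
#' every third codon position, pooled across sequences. In lenient mode N
#' is allowed and excluded from both denominators. Sequences whose length
#' is not a multiple of 3 are excluded from GC3 with a warning (strict
#' mode: error).
#'
#' @param cds a [Biostrings::DNAStringSet] or named character vector.
#' @param excludeStop drop a terminal stop codon (TAA/TAG/TGA) from GC3.
#' @param mode `"strict"` or `"lenient"`.
#' @return Named numeric: `gc`, `gc3` (percent).
#' @export
gcMetrics <- function(cds, excludeStop = FALSE,
                      mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  seqs <- toupper(.asSequenceVector(cds, "cds"))
  allowed <- if (mode == "strict") "ACGT" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad))
    stop("CDS contains letters outside ", allowed, call. = FALSE)
  gcCount <- atCount <- gc3Count <- at3Count <- 0
  offFrame <- nchar(seqs) %% 3L != 0L
  if (any(offFrame)) {
    msg <- sprintf("%d CDS with length not divisible by 3 excluded from GC3",
                   sum(offFrame))
    if (mode == "strict") stop(msg, call. = FALSE) else warning(msg)
  }
  stops <- c("TAA", "TAG", "TGA")
  gcChars <- utf8ToInt("GC")
  atChars <- utf8ToInt("AT")
  for (i in seq_along(seqs)) {
    v <- utf8ToInt(seqs[i])
    gcCount <- gcCount + sum(v %in% gcChars)
    atCount <- atCount + sum(v %in% atChars)
    if (offFrame[i]) next
    L <- length(v)
    third <- v[seq.int(3L, L, 3L)]
    if (excludeStop &&
        substr(seqs[i], L - 2L, L) %in% stops)
      third <- third[-length(third)]
    gc3Count <- gc3Count + sum(third %in% gcChars)
    at3Count <- at3Count + sum(third %in% atChars)
  }
  if (gcCount + atCount == 0)
    stop("no A/C/G/T positions found", call. = FALSE)
  c(gc = 100 * gcCount / (gcCount + atCount),
    gc3 = if (gc3Count + at3Count > 0)
      100 * gc3Count / (gc3Count + at3Count) else NA_real_)
}

# EMBOSS pKa values: side chains plus termini.
.pkaEmboss <- list(
  positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
  negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

#' Isoelectric point of a protein sequence
#'
#' Net charge as a function of pH is modelled by Henderson-Hasselbalch
#' terms for the ionisable side chains (D, E, C, Y, H, K, R) plus the two
#' termini, with the EMBOSS pKa set; the pI is located by bisection on
#' \[0, 14\] to |charge| < 1e-4.
#'
#' @param seqs protein sequence(s): character vector or
#'   [Biostrings::AAStringSet]; canonical residues only.
#' @param pka optional replacement pKa set, a list with named numeric
#'   elements `positive` (must include `Nterm`) and `negative` (must
#'   include `Cterm`).
#' @return Numeric vector of pI values, one per sequence.
#' @export
isoelectricPoint <- function(seqs, pka = .pkaEmboss) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (any(nchar(seqs) == 0L))
    stop("sequences must be non-empty", call. = FALSE)
  names(seqs) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  .checkAlphabet(seqs, "strict")
  vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1L]]
    countOf <- function(nm) {
      if (nm %in% c("Nterm", "Cterm")) 1 else sum(chars == nm)
    }
    nPos <- vapply(names(pka$positive), countOf, numeric(1L))
    nNeg <- vapply(names(pka$negative), countOf, numeric(1L))
    charge <- function(ph) {
      sum(nPos / (1 + 10^(ph - pka$positive))) -
        sum(nNeg / (1 + 10^(pka$negative - ph)))
    }
    lo <- 0; hi <- 14
    for (it in seq_len(200L)) {
      mid <- (lo + hi) / 2
      q <- charge(mid)
      if (abs(q) < 1e-4) break
      if (q > 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1L))
}

#' Mean isoelectric point of a proteome
#'
#' Unweighted mean of the per-sequence pI values.
#'
#' @inheritParams isoelectricPoint
#' @return A single number.
#' @export
meanIsoelectricPoint <- function(seqs, pka = .pkaEmboss) {
  mean(isoelectricPoint(seqs, pka = pka))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' COG-category outliers by the two-standard-deviation rule
#'
#' Converts counts to within-organism proportions, then flags each
#' category of the focal organism whose proportion lies more than two
#' sample standard deviations (n-1 denominator) from the mean of the
#' reference organisms: `"high"` above, `"low"` below. With a
#' zero-variance reference, any deviation of the focal proportion is
#' flagged; equality is not.
#'
#' @param table matrix or data.frame of counts, organisms in rows,
#'   COG categories in columns.
#' @param focal name of the focal organism (not among `refs`).
#' @param refs names of at least two reference organisms.
#' @return data.frame: `category`, `focal_prop`, `ref_mean`, `ref_sd`,
#'   `flag` (`"high"`, `"low"`, `"none"`).
#' @export
cogOutliers <- function(table, focal, refs) {
  table <- as.matrix(table)
  if (!focal %in% rownames(table))
    stop("focal organism not found in table", call. = FALSE)
  if (focal %in% refs)
    stop("focal organism must not be among the references", call. = FALSE)
  if (length(refs) < 2L || !all(refs %in% rownames(table)))
    stop("need at least two reference organisms present in the table",
         call. = FALSE)
  props <- sweep(table, 1L, rowSums(table), "/")
  fp <- props[focal, ]
  rm <- colMeans(props[refs, , drop = FALSE])
  rs <- apply(props[refs, , drop = FALSE], 2L, stats::sd)
  flag <- ifelse(fp > rm + 2 * rs, "high",
                 ifelse(fp < rm - 2 * rs, "low", "none"))
  data.frame(category = colnames(table), focal_prop = as.numeric(fp),
             ref_mean = as.numeric(rm), ref_sd = as.numeric(rs),
             flag = as.character(flag), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Genomic signature vectors: tetranucleotide frequencies and RSCU
#'
#' Tetranucleotides are counted in overlapping windows on the given
#' strand (optionally pooled with the reverse complement) and normalised
#' to a 256-entry frequency vector. Codon usage is pooled over all
#' sequences and expressed as relative synonymous codon usage, RSCU =
#' observed count x family size / family total, for the 61 sense codons
#' of the standard genetic code.
#'
#' @param cds a [Biostrings::DNAStringSet] or named character vector of
#'   in-frame coding sequences.
#' @param bothStrands pool tetranucleotide counts with the reverse
#'   complement strand.
#' @return A list: `tetra` (named numeric, sums to 1), `codonCounts`
#'   (named integer, 64 codons) and `rscu` (data.frame `codon`, `aa`,
#'   `count`, `rscu`; `NA` RSCU for unobserved families).
#' @export
genomicSignatures <- function(cds, bothStrands = FALSE) {
  x <- if (methods::is(cds, "DNAStringSet")) cds
       else Biostrings::DNAStringSet(.asSequenceVector(cds, "cds"))
  if (any(Biostrings::width(x) < 4L))
    message(sum(Biostrings::width(x) < 4L),
            " sequence(s) shorter than 4 nt contribute no tetranucleotides")
  tetra <- colSums(Biostrings::oligonucleotideFrequency(x, width = 4L))
  if (bothStrands)
    tetra <- tetra + colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(x), width = 4L))
  if (sum(tetra) == 0)
    stop("no tetranucleotides counted", call. = FALSE)
  tetra <- tetra / sum(tetra)

  codonCounts <- colSums(Biostrings::oligonucleotideFrequency(
    x, width = 3L, step = 3L))
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  aa <- gc[sense]
  famSize <- table(aa)[aa]
  famTotal <- tapply(codonCounts[sense], aa, sum)[aa]
  rscu <- ifelse(famTotal > 0,
                 codonCounts[sense] * as.numeric(famSize) /
                   as.numeric(famTotal), NA_real_)
  list(tetra = tetra, codonCounts = codonCounts,
       rscu = data.frame(codon = sense, aa = as.character(aa),
                         count = as.numeric(codonCounts[sense]),
                         rscu = as.numeric(rscu),
                         stringsAsFactors = FALSE, row.names = NULL))
}
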