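# Central S4 containers.

#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' AlignedPair: a gapped global alignment of one ortholog pair
#'
#' Holds the two gapped sequences of a pairwise global alignment plus ids
#' and the alignment score. Ungapped-column and identity statistics are
#' derived by the accessors, never stored redundantly.
#'
#' @slot idA,idB sequence identifiers.
#' @slot alnA,alnB gapped sequences (gap character `-`), equal length.
#' @slot score numeric alignment score.
#' @exportClass AlignedPair
setClass("AlignedPair",
  representation(idA = "character", idB = "character",
                 alnA = "character", alnB = "character",
                 score = "numeric"))

setValidity("AlignedPair", function(object) {
  if (nchar(object@alnA) != nchar(object@alnB))
    return("gapped sequences must have equal length")
  a <- strsplit(object@alnA, "")[[1]]
  b <- strsplit(object@alnB, "")[[1]]
  if (any(a == "-" & b == "-"))
    return("alignment contains a column gapped in both rows")
  TRUE
})

#' OrthologSet: reciprocal-best-hit ortholog pairs with their alignments
#'
#' One row per ortholog pair: ids, gapped sequences, score, identity and
#' coverage statistics. Each gene id occurs in at most one pair.
#'
#' @slot pairs a [S4Vectors::DataFrame] with columns `id_a`, `id_b`,
#'   `aln_a`, `aln_b`, `score`, `n_ungapped`, `n_identical`, `identity`,
#'   `coverage_a`, `coverage_b`.
#' @slot organisms length-2 character: reference (A) and comparison (B)
#'   organism labels.
#' @exportClass OrthologSet
setClass("OrthologSet",
  representation(pairs = "DataFrame", organisms = "character"))

setValidity("OrthologSet", function(object) {
  need <- c("id_a", "id_b", "aln_a", "aln_b", "score", "n_ungapped",
            "n_identical", "identity", "coverage_a", "coverage_b")
  if (!all(need %in% colnames(object@pairs)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (length(object@organisms) != 2L)
    return("organisms must have length 2")
  if (anyDuplicated(object@pairs$id_a) || anyDuplicated(object@pairs$id_b))
    return("a gene id occurs in more than one pair")
  if (any(object@pairs$n_identical > object@pairs$n_ungapped))
    return("n_identical exceeds n_ungapped")
  TRUE
})

#' DirectedSubstitutionMatrix: 20x20 residue state counts
#'
#' Counts of ungapped alignment columns by (reference-organism residue,
#' comparison-organism residue). The diagonal holds conserved positions;
#' cell \[a, b\] off the diagonal counts positions where the reference
#' organism carries `a` and the comparison organism `b`.
#'
#' @slot counts integer 20x20 matrix, residues ordered as [aaAlphabet()];
#'   rows are the reference organism's states.
#' @slot refOrganism,cmpOrganism organism labels for rows and columns.
#' @exportClass DirectedSubstitutionMatrix
setClass("DirectedSubstitutionMatrix",
  representation(counts = "matrix", refOrganism = "character",
                 cmpOrganism = "character"))

setValidity("DirectedSubstitutionMatrix", function(object) {
  m <- object@counts
  if (!identical(dim(m), c(20L, 20L)))
    return("counts must be 20x20")
  if (!identical(rownames(m), aaAlphabet()) ||
      !identical(colnames(m), aaAlphabet()))
    return("counts must be ordered by aaAlphabet() on both margins")
  if (any(m < 0) || any(m != round(m)))
    return("counts must be non-negative integers")
  TRUE
})

#' Construct a DirectedSubstitutionMatrix
#'
#' @param counts 20x20 non-negative integer matrix with residues in the
#'   [aaAlphabet()] ordering on both margins (dimnames are enforced).
#' @param refOrganism,cmpOrganism labels of the row (reference) and column
#'   (comparison) organisms.
#' @return A [DirectedSubstitutionMatrix-class] object.
#' @export
DirectedSubstitutionMatrix <- function(counts,
                                       refOrganism = "organism_A",
                                       cmpOrganism = "organism_B") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(aaAlphabet(), aaAlphabet())
  methods::new("DirectedSubstitutionMatrix", counts = counts,
               refOrganism = refOrganism, cmpOrganism = cmpOrganism)
}
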