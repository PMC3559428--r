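# Generics and accessor methods for the S4 containers.

#' @rdname OrthologSet-class
#' @param x an object.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname OrthologSet-class
#' @export
setGeneric("totalPositions", function(x) standardGeneric("totalPositions"))

#' @rdname DirectedSubstitutionMatrix-class
#' @param x an object.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname DirectedSubstitutionMatrix-class
#' @export
setGeneric("refOrganism", function(x) standardGeneric("refOrganism"))

#' @rdname DirectedSubstitutionMatrix-class
#' @export
setGeneric("cmpOrganism", function(x) standardGeneric("cmpOrganism"))

#' @rdname AlignedPair-class
#' @param x an object.
#' @export
setGeneric("nUngappedColumns", function(x) standardGeneric("nUngappedColumns"))

#' @rdname AlignedPair-class
#' @export
setGeneric("nIdentical", function(x) standardGeneric("nIdentical"))

## ---- AlignedPair ----

#' @rdname AlignedPair-class
#' @export
setMethod("nUngappedColumns", "AlignedPair", function(x) {
  gap <- utf8ToInt("-")
  sum(utf8ToInt(x@alnA) != gap & utf8ToInt(x@alnB) != gap)
})

#' @rdname AlignedPair-class
#' @export
setMethod("nIdentical", "AlignedPair", function(x) {
  gap <- utf8ToInt("-")
  ca <- utf8ToInt(x@alnA)
  cb <- utf8ToInt(x@alnB)
  a <- .aaIndex[ca]
  b <- .aaIndex[cb]
  sum(ca != gap & cb != gap & !is.na(a) & !is.na(b) & a == b, na.rm = TRUE)
})

setMethod("show", "AlignedPair", function(object) {
  cat("AlignedPair:", object@idA, "vs", object@idB, "\n")
  cat("  alignment length:", nchar(object@alnA),
      "| ungapped:", nUngappedColumns(object),
      "| identical:", nIdentical(object),
      "| score:", object@score, "\n")
})

## ---- OrthologSet ----

#' @rdname OrthologSet-class
#' @export
setMethod("nPairs", "OrthologSet", function(x) nrow(x@pairs))

#' @rdname OrthologSet-class
#' @export
setMethod("totalPositions", "OrthologSet", function(x) sum(x@pairs$n_ungapped))

#' @rdname OrthologSet-class
#' @export
setMethod("as.data.frame", "OrthologSet", function(x, ...) {
  as.data.frame(x@pairs)
})

setMethod("show", "OrthologSet", function(object) {
  cat("OrthologSet:", nPairs(object), "ortholog pairs (",
      object@organisms[1L], "vs", object@organisms[2L], ")\n")
  cat("  total ungapped positions:", totalPositions(object), "\n")
  if (nPairs(object) > 0L) {
    cat("  mean identity:",
        sprintf("%.1f%%", mean(object@pairs$identity)), "\n")
  }
})

## ---- DirectedSubstitutionMatrix ----

#' @rdname DirectedSubstitutionMatrix-class
#' @export
setMethod("counts", "DirectedSubstitutionMatrix", function(x) x@counts)

#' @rdname DirectedSubstitutionMatrix-class
#' @export
setMethod("refOrganism", "DirectedSubstitutionMatrix", function(x) x@refOrganism)

#' @rdname DirectedSubstitutionMatrix-class
#' @export
setMethod("cmpOrganism", "DirectedSubstitutionMatrix", function(x) x@cmpOrganism)

setMethod("show", "DirectedSubstitutionMatrix", function(object) {
  m <- object@counts
  cat("DirectedSubstitutionMatrix (rows =", object@refOrganism,
      ", cols =", object@cmpOrganism, ")\n")
  cat("  total positions:", sum(m),
      "| conserved:", sum(diag(m)),
      "| substituted:", sum(m) - sum(diag(m)), "\n")
})

#' Transpose a directed substitution matrix
#'
#' Swapping the two organisms transposes the count table.
#'
#' @param x a [DirectedSubstitutionMatrix-class].
#' @return The matrix with organisms and counts transposed.
#' @export
setMethod("t", "DirectedSubstitutionMatrix", function(x) {
  DirectedSubstitutionMatrix(t(x@counts), refOrganism = x@cmpOrganism,
                             cmpOrganism = x@refOrganism)
})
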