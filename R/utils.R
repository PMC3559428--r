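# Shared constants and small internal helpers.

#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the fixed ordering used by every matrix
#' and composition vector in this package.
#'
#' @return Character vector of length 20.
#' @export
aaAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# ASCII lookup: maps utf8 codes of residue letters to 1..20, gap "-" and
# unknowns to NA. Built once at load.
.aaIndex <- local({
  idx <- rep(NA_integer_, 128L)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  idx[utf8ToInt(paste0(aa, collapse = ""))] <- seq_len(20L)
  idx
})

#' Average amino-acid frequencies of a standard proteome
#'
#' Background residue frequencies (Swiss-Prot averages) used as the default
#' ancestral composition by [simulateOrthologProteomes()].
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
standardAaFrequencies <- function() {
  f <- c(A = 0.0825, C = 0.0138, D = 0.0545, E = 0.0672, F = 0.0386,
         G = 0.0707, H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0965,
         M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0393, R = 0.0553,
         S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292)
  f / sum(f)
}

.assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.assertNonNeg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single finite value >= 0", name), call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

.assertPercent <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 100)
    stop(sprintf("'%s' must be a percentage in [0, 100]", name), call. = FALSE)
  invisible(x)
}

# Coerce a proteome argument to a named character vector of sequences.
.asSequenceVector <- function(x, what = "proteome") {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop(sprintf("'%s' must be an XStringSet or a named character vector",
                 what), call. = FALSE)
  }
  if (length(out) == 0L)
    stop(sprintf("'%s' is empty", what), call. = FALSE)
  if (is.null(names(out)) || anyDuplicated(names(out)))
    stop(sprintf("'%s' must have unique sequence names", what), call. = FALSE)
  out
}

# Residue integer codes (1..20) of one sequence string; NA for non-canonical.
.seqToCodes <- function(s) {
  codes <- utf8ToInt(s)
  codes[codes > 128L] <- 1L  # out-of-range maps to NA via index below
  .aaIndex[codes]
}

.codesToSeq <- function(codes) {
  intToUtf8(utf8ToInt(paste0(aaAlphabet(), collapse = ""))[codes])
}
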