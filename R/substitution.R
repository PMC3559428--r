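# Directional substitution matrix over ungapped alignment columns and the
# per-exchange chi-squared asymmetry test against the 50:50 expectation.

#' Count residue states over ungapped alignment columns
#'
#' For every alignment column with no gap (and, in lenient inputs, no X)
#' in either row, increments the cell indexed by (reference-organism
#' residue, comparison-organism residue). The diagonal therefore counts
#' conserved positions and the grand total equals the number of
#' analyzable columns summed over pairs.
#'
#' @param orthologs an [OrthologSet-class].
#' @return A [DirectedSubstitutionMatrix-class].
#' @export
countSubstitutions <- function(orthologs) {
  stopifnot(methods::is(orthologs, "OrthologSet"))
  if (nPairs(orthologs) == 0L) {
    warning("empty ortholog set: returning an all-zero matrix")
    return(DirectedSubstitutionMatrix(
      matrix(0L, 20L, 20L),
      refOrganism = orthologs@organisms[1L],
      cmpOrganism = orthologs@organisms[2L]))
  }
  a <- .aaIndex[utf8ToInt(paste0(orthologs@pairs$aln_a, collapse = ""))]
  b <- .aaIndex[utf8ToInt(paste0(orthologs@pairs$aln_b, collapse = ""))]
  keep <- !is.na(a) & !is.na(b)
  m <- matrix(tabulate((a[keep] - 1L) * 20L + b[keep], nbins = 400L),
              nrow = 20L, byrow = TRUE)
  DirectedSubstitutionMatrix(m, refOrganism = orthologs@organisms[1L],
                             cmpOrganism = orthologs@organisms[2L])
}

#' Chi-squared test of directional asymmetry for one residue exchange
#'
#' Tests the two directed counts of an exchange pair against the expected
#' 50:50 ratio with a one-degree-of-freedom goodness-of-fit statistic,
#' `chi2 = (x - y)^2 / (x + y)`. The exact two-sided binomial test
#' (`Binomial(x + y, 1/2)`) is available as an alternative.
#'
#' @param x,y non-negative integer directed counts (`a -> b` and
#'   `b -> a`).
#' @param a,b optional residue labels carried into the result.
#' @param alpha significance level (default 0.0005, no multiple-testing
#'   correction).
#' @param method `"chisq"` (default) or `"binomial"` (exact).
#' @return One-row data.frame: `a`, `b`, `x`, `y`, `chi2`, `p`,
#'   `significant`, `direction` (the residue gaining net counts, `NA` on
#'   ties). When `x + y = 0` the test is undefined and is reported as
#'   non-significant with `p = 1`.
#' @export
chiSquareAsymmetry <- function(x, y, a = NA_character_, b = NA_character_,
                               alpha = 0.0005,
                               method = c("chisq", "binomial")) {
  method <- match.arg(method)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L ||
      length(y) != 1L || x < 0 || y < 0 || x != round(x) || y != round(y))
    stop("'x' and 'y' must be single non-negative integers", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  n <- x + y
  if (n == 0) {
    chi2 <- 0
    p <- 1
  } else if (method == "chisq") {
    chi2 <- (x - y)^2 / n
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  } else {
    chi2 <- (x - y)^2 / n
    p <- stats::binom.test(round(x), round(n), p = 0.5)$p.value
  }
  direction <- if (n == 0 || x == y) NA_character_ else if (x > y) b else a
  data.frame(a = a, b = b, x = x, y = y, chi2 = chi2, p = p,
             significant = (n > 0) && (p < alpha), direction = direction,
             stringsAsFactors = FALSE)
}

#' Asymmetry tests for all unordered residue pairs of a matrix
#'
#' Runs [chiSquareAsymmetry()] on the two directed counts of each of the
#' 190 unordered residue pairs. By default the raw threshold is applied
#' with no multiple-testing correction; Bonferroni and Benjamini-Hochberg
#' adjustments are available.
#'
#' @param m a [DirectedSubstitutionMatrix-class].
#' @param alpha significance level (default 0.0005).
#' @param method `"chisq"` or `"binomial"`.
#' @param correction `"none"` (default), `"bonferroni"` or `"BH"`;
#'   applied to the p-values before thresholding.
#' @return data.frame with one row per pair, columns as in
#'   [chiSquareAsymmetry()] plus `p_adj`, sorted by p ascending with
#'   alphabetical pair order breaking ties.
#' @export
testAllPairs <- function(m, alpha = 0.0005, method = c("chisq", "binomial"),
                         correction = c("none", "bonferroni", "BH")) {
  stopifnot(methods::is(m, "DirectedSubstitutionMatrix"))
  method <- match.arg(method)
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  aa <- aaAlphabet()
  cmb <- utils::combn(20L, 2L)
  cnt <- counts(m)
  res <- vector("list", ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1L, k]
    j <- cmb[2L, k]
    res[[k]] <- chiSquareAsymmetry(cnt[i, j], cnt[j, i], a = aa[i],
                                   b = aa[j], alpha = alpha, method = method)
  }
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p,
    method = switch(correction, none = "none", bonferroni = "bonferroni",
                    BH = "BH"))
  out$significant <- (out$x + out$y > 0) & (out$p_adj < alpha)
  out[out$x + out$y == 0, "direction"] <- NA_character_
  out[order(out$p, out$a, out$b), , drop = FALSE]
}

#' Per-residue replacement bookkeeping
#'
#' Summarises, for each residue of the reference organism, how often it
#' was replaced (row off-diagonal total), how often it was gained (column
#' off-diagonal total), the net excess (replaced minus gained) and the
#' net excess as a percentage of the residue's full row total (conserved
#' plus replaced). Preferred acceptor residues are those that are the
#' significant gaining direction in at least `minPairs` exchange pairs.
#'
#' @param m a [DirectedSubstitutionMatrix-class].
#' @param results output of [testAllPairs()]; computed from `m` when
#'   omitted.
#' @param minPairs minimum number of significant pairs for a residue to
#'   count as a preferred acceptor (default 3).
#' @return A list: `perResidue` (data.frame `residue`, `replaced`,
#'   `gained`, `netExcess`, `netPct`) and `preferredAcceptors`
#'   (character vector).
#' @export
replacementSummary <- function(m, results = NULL, minPairs = 3L) {
  stopifnot(methods::is(m, "DirectedSubstitutionMatrix"))
  if (is.null(results)) results <- testAllPairs(m)
  cnt <- counts(m)
  rowTot <- rowSums(cnt)
  replaced <- rowTot - diag(cnt)
  gained <- colSums(cnt) - diag(cnt)
  net <- replaced - gained
  perResidue <- data.frame(
    residue = aaAlphabet(), replaced = as.numeric(replaced),
    gained = as.numeric(gained), netExcess = as.numeric(net),
    netPct = ifelse(rowTot > 0, 100 * net / rowTot, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
  sig <- results[results$significant & !is.na(results$direction), ]
  preferred <- if (nrow(sig) > 0L) {
    accTab <- table(sig$direction)
    names(accTab)[accTab >= minPairs]
  } else character(0)
  list(perResidue = perResidue,
       preferredAcceptors = sort(as.character(preferred)))
}

#' Read and write directed substitution matrices as TSV
#'
#' The dialect is a tab-separated table with a one-letter residue header
#' row and first column, residues in the fixed [aaAlphabet()] ordering.
#'
#' @param m a [DirectedSubstitutionMatrix-class].
#' @param path file path.
#' @param refOrganism,cmpOrganism organism labels attached on read.
#' @return `writeSubstitutionMatrix` returns `path` invisibly;
#'   `readSubstitutionMatrix` returns a
#'   [DirectedSubstitutionMatrix-class].
#' @export
writeSubstitutionMatrix <- function(m, path) {
  stopifnot(methods::is(m, "DirectedSubstitutionMatrix"))
  df <- data.frame(AA = rownames(counts(m)), counts(m),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSubstitutionMatrix
#' @export
readSubstitutionMatrix <- function(path, refOrganism = "organism_A",
                                   cmpOrganism = "organism_B") {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!identical(df[[1L]], aaAlphabet()) ||
      !identical(colnames(df)[-1L], aaAlphabet()))
    stop("matrix file must use the fixed residue ordering on both margins",
         call. = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df[[1L]]
  DirectedSubstitutionMatrix(m, refOrganism = refOrganism,
                             cmpOrganism = cmpOrganism)
}
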