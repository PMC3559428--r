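# Packaged fixtures: the published 20x20 ortholog substitution count table
# for the piezophilic/non-piezophilic Desulfovibrio comparison, and the
# two-condition differential-abundance protein tables. Both are versioned
# transcriptions guarded by checksums against drift.

.fixtureChecksums <- c(
  table1_aa_substitutions.tsv = "cb93f6144f00dce4d3e2495b180936bf",
  tables23_differential_abundance.tsv = "102baba958047b947443deb28b784e01")

.fixturePath <- function(file) {
  path <- system.file("extdata", file, package = "OrthoAsym",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixtureChecksums[[file]])))
    stop("fixture checksum mismatch for ", file,
         ": the packaged transcription has drifted", call. = FALSE)
  path
}

#' Published ortholog substitution count table
#'
#' Loads the packaged transcription of the published 20x20 directed
#' substitution count table for 1,911 ortholog pairs between
#' *D. salexigens* (rows, reference) and *D. piezophilus* (columns). A
#' checksum mismatch is a hard error.
#'
#' @return A [DirectedSubstitutionMatrix-class].
#' @export
loadTable1Fixture <- function() {
  readSubstitutionMatrix(.fixturePath("table1_aa_substitutions.tsv"),
                         refOrganism = "D. salexigens",
                         cmpOrganism = "D. piezophilus")
}

#' Published differential-abundance protein tables
#'
#' Loads the packaged transcription of the published tables of protein
#' spots with increased (24 entries) or decreased (16 entries) abundance
#' under low (0.1 MPa) relative to high (10 MPa) hydrostatic pressure.
#' One spot was detected in only one condition and carries `NA`
#' differential abundance (a qualitative presence/absence difference,
#' retained as significant). The published tables print their DA values
#' with a stated uncertainty of 0.2, stored as the `da_uncertainty`
#' attribute and unused in computation.
#'
#' @return data.frame with columns `spot`, `accession`, `annotation`,
#'   `cog_category`, `da`, `direction`
#'   (`"increased_low"`/`"decreased_low"`).
#' @export
loadDaFixture <- function() {
  df <- utils::read.delim(
    .fixturePath("tables23_differential_abundance.tsv"),
    stringsAsFactors = FALSE)
  need <- c("spot", "accession", "annotation", "cog_category", "da",
            "direction")
  if (!identical(colnames(df), need))
    stop("malformed differential-abundance fixture: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(df$direction %in% c("increased_low", "decreased_low")))
    stop("malformed differential-abundance fixture: bad direction values",
         call. = FALSE)
  attr(df, "da_uncertainty") <- 0.2
  df
}
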