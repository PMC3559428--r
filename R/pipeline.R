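# End-to-end pipeline: reciprocal best hits -> alignments -> directed
# substitution matrix -> asymmetry tests -> summaries, plus the optional
# composition, GC/signature, COG-outlier and differential-abundance
# stages, all written as TSV/FASTA/Newick with a JSON run manifest.

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Comma-separated
#' values become vectors; numeric-looking values are converted.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    val <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

.stage <- function(name, expr, quiet) {
  if (!quiet) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Write an ortholog set as TSV plus aligned FASTA
#'
#' @param os an [OrthologSet-class].
#' @param tsv,fasta output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
writeOrthologSet <- function(os, tsv = NULL, fasta = NULL) {
  df <- as.data.frame(os)
  if (!is.null(tsv)) {
    utils::write.table(
      df[, c("id_a", "id_b", "score", "identity", "coverage_a",
             "coverage_b")],
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta)) {
    recs <- character(2L * nrow(df))
    recs[c(TRUE, FALSE)] <- sprintf(">%s\n%s", df$id_a, df$aln_a)
    recs[c(FALSE, TRUE)] <- sprintf(">%s\n%s", df$id_b, df$aln_b)
    writeLines(recs, fasta)
  }
  invisible(c(tsv, fasta))
}

#' Run the comparative pipeline end to end
#'
#' Mandatory inputs are the two proteomes; the remaining stages run when
#' their inputs are provided and are skipped (with a log line) otherwise.
#' All outputs are tab-separated (trees as Newick) and a `manifest.json`
#' records parameters, seed and output checksums, sufficient to
#' reproduce the run bit-exactly.
#'
#' @param config named list (or path to a key=value file, see
#'   [readPipelineConfig()]) with entries: `proteome_a`, `proteome_b`
#'   (FASTA paths or AAStringSet), `out_dir`; optional `cds` (FASTA
#'   path/DNAStringSet), `composition_proteomes` (named vector of FASTA
#'   paths, >= 3 for a tree), `cog_table` (TSV path, organisms x
#'   categories), `cog_focal`, `cog_refs`, `spot_table` (TSV path),
#'   `min_identity` (30), `min_coverage` (70), `alpha` (0.0005),
#'   `da_threshold` (1.5), `seed` (1).
#' @param quiet suppress stage log messages.
#' @return Invisibly, a list with the computed objects (`orthologs`,
#'   `matrix`, `tests`, `summary`, and any optional stage results).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- readPipelineConfig(config)
  getOr <- function(key, default) config[[key]] %||% default
  outDir <- config$out_dir
  if (is.null(outDir)) stop("config must set 'out_dir'", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  minIdentity <- getOr("min_identity", 30)
  minCoverage <- getOr("min_coverage", 70)
  alpha <- getOr("alpha", 0.0005)
  daThreshold <- getOr("da_threshold", 1.5)
  seed <- getOr("seed", 1L)
  set.seed(seed)
  results <- list()

  loadAA <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
      Biostrings::readAAStringSet(x)
    else x
  }
  a <- .stage("read_proteomes", loadAA(config$proteome_a), quiet)
  b <- .stage("read_proteomes", loadAA(config$proteome_b), quiet)

  results$orthologs <- .stage("reciprocal_best_hits",
    reciprocalBestHits(a, b, minIdentity = minIdentity,
                       minCoverage = minCoverage), quiet)
  writeOrthologSet(results$orthologs,
                   tsv = file.path(outDir, "orthologs.tsv"),
                   fasta = file.path(outDir, "alignments.fasta"))

  results$matrix <- .stage("count_substitutions",
    countSubstitutions(results$orthologs), quiet)
  writeSubstitutionMatrix(results$matrix,
                          file.path(outDir, "substitution_matrix.tsv"))

  results$tests <- .stage("asymmetry_tests",
    testAllPairs(results$matrix, alpha = alpha), quiet)
  utils::write.table(results$tests,
                     file.path(outDir, "asymmetry_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  results$summary <- .stage("replacement_summary",
    replacementSummary(results$matrix, results$tests), quiet)
  utils::write.table(results$summary$perResidue,
                     file.path(outDir, "replacement_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(config$cds)) {
    cds <- if (is.character(config$cds))
      Biostrings::readDNAStringSet(config$cds) else config$cds
    results$gc <- .stage("gc_metrics", gcMetrics(cds), quiet)
    results$signatures <- .stage("genomic_signatures",
                                 genomicSignatures(cds), quiet)
    utils::write.table(
      data.frame(metric = names(results$gc), value = results$gc),
      file.path(outDir, "gc_metrics.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(results$signatures$rscu,
                       file.path(outDir, "codon_usage_rscu.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(tetranucleotide = names(results$signatures$tetra),
                 frequency = as.numeric(results$signatures$tetra)),
      file.path(outDir, "tetranucleotide_frequencies.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (!quiet) message("[gc_metrics] skipped: no CDS input")

  results$pi <- .stage("isoelectric_point", c(
    mean_pi_a = meanIsoelectricPoint(a),
    mean_pi_b = meanIsoelectricPoint(b)), quiet)
  utils::write.table(
    data.frame(proteome = names(results$pi), mean_pi = results$pi),
    file.path(outDir, "isoelectric_points.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  if (!is.null(config$composition_proteomes)) {
    comps <- .stage("composition_tree", {
      sets <- lapply(config$composition_proteomes, loadAA)
      do.call(rbind, lapply(sets, aaFrequency))
    }, quiet)
    d <- compositionDistanceMatrix(comps)
    utils::write.table(data.frame(label = rownames(d), d),
                       file.path(outDir, "composition_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(d) >= 3L) {
      results$tree <- neighborJoining(d)
      ape::write.tree(results$tree,
                      file.path(outDir, "composition_tree.nwk"))
    }
    results$compositions <- comps
  } else if (!quiet) {
    message("[composition_tree] skipped: no composition proteomes")
  }

  if (!is.null(config$cog_table)) {
    cog <- as.matrix(utils::read.delim(config$cog_table, row.names = 1L,
                                       check.names = FALSE))
    results$cog <- .stage("cog_outliers",
      cogOutliers(cog, config$cog_focal, config$cog_refs), quiet)
    utils::write.table(results$cog, file.path(outDir, "cog_outliers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (!quiet) message("[cog_outliers] skipped: no COG table")

  if (!is.null(config$spot_table)) {
    spots <- if (is.character(config$spot_table))
      readSpotTable(config$spot_table) else config$spot_table
    results$da <- .stage("differential_abundance",
      differentialAbundance(spots, threshold = daThreshold), quiet)
    utils::write.table(results$da,
                       file.path(outDir, "differential_abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (!quiet) {
    message("[differential_abundance] skipped: no spot table")
  }

  outputs <- list.files(outDir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "OrthoAsym",
    version = as.character(utils::packageVersion("OrthoAsym")),
    parameters = list(min_identity = minIdentity,
                      min_coverage = minCoverage, alpha = alpha,
                      da_threshold = daThreshold, seed = seed),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
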