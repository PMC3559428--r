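# Two-condition gel-spot differential abundance: per-gel normalisation of
# spot volumes and the ratio filter used for significance calls.

#' Read a long-format spot-volume table
#'
#' @param path TSV with columns `spot_id`, `condition`, `replicate`,
#'   `volume`.
#' @return data.frame.
#' @export
readSpotTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "condition", "replicate", "volume")
  if (!all(need %in% colnames(df)))
    stop("spot table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Differential abundance of spots between two conditions
#'
#' Within each gel (condition x replicate) volumes are normalised to
#' relative volumes (volume over the gel's total); replicates are then
#' averaged per condition. The differential abundance of a spot is the
#' ratio of the larger to the smaller relative volume, with the direction
#' naming the condition of higher abundance. Significance uses the
#' inclusive rule `DA >= threshold` (set `strict = TRUE` for a strict
#' inequality); spots quantified in only one condition are flagged
#' significant with undefined DA.
#'
#' @param table long-format data.frame (`spot_id`, `condition`,
#'   `replicate`, `volume`); `replicate` defaults to 1 when absent.
#' @param threshold abundance ratio considered significant (>= 1;
#'   default 1.5).
#' @param strict use `DA > threshold` instead of `DA >= threshold`.
#' @param normalize `"total"` (per-gel relative volumes, default) or
#'   `"none"` (use raw volumes).
#' @return data.frame: `spot_id`, one `rel_*` column per condition,
#'   `da`, `direction`, `significant`, `missing_data`.
#' @export
differentialAbundance <- function(table, threshold = 1.5, strict = FALSE,
                                  normalize = c("total", "none")) {
  normalize <- match.arg(normalize)
  if (!is.numeric(threshold) || threshold < 1)
    stop("'threshold' must be >= 1", call. = FALSE)
  if (!all(c("spot_id", "condition", "volume") %in% colnames(table)))
    stop("table needs columns spot_id, condition, volume", call. = FALSE)
  if (is.null(table$replicate)) table$replicate <- 1L
  conds <- unique(table$condition)
  if (length(conds) != 2L)
    stop("exactly two conditions are required", call. = FALSE)
  allSpots <- unique(table$spot_id)
  table <- table[!is.na(table$volume), , drop = FALSE]
  if (any(table$volume <= 0))
    stop("volumes must be strictly positive", call. = FALSE)
  if (nrow(table) == 0L)
    stop("no quantified spots", call. = FALSE)
  unquantified <- setdiff(allSpots, unique(table$spot_id))
  if (length(unquantified))
    stop("spot(s) missing in both conditions: ",
         paste(utils::head(unquantified, 3L), collapse = ", "),
         call. = FALSE)

  # Per-gel relative volumes, then replicate means per condition.
  gel <- interaction(table$condition, table$replicate, drop = TRUE)
  rel <- if (normalize == "total")
    table$volume / ave(table$volume, gel, FUN = sum)
  else table$volume
  spots <- unique(table$spot_id)
  relMat <- matrix(NA_real_, length(spots), 2L,
                   dimnames = list(spots, conds))
  for (cc in conds) {
    sel <- table$condition == cc
    mm <- tapply(rel[sel], table$spot_id[sel], mean)
    relMat[names(mm), cc] <- mm
  }
  bothMissing <- rowSums(is.na(relMat)) == 2L
  if (any(bothMissing))
    stop("spot(s) missing in both conditions: ",
         paste(utils::head(spots[bothMissing], 3L), collapse = ", "),
         call. = FALSE)
  missing <- rowSums(is.na(relMat)) == 1L
  hi <- pmax(relMat[, 1L], relMat[, 2L])
  lo <- pmin(relMat[, 1L], relMat[, 2L])
  da <- ifelse(missing, NA_real_, hi / lo)
  direction <- ifelse(is.na(relMat[, 1L]), conds[2L],
               ifelse(is.na(relMat[, 2L]), conds[1L],
               ifelse(relMat[, 1L] > relMat[, 2L], conds[1L],
               ifelse(relMat[, 2L] > relMat[, 1L], conds[2L],
                      NA_character_))))
  sig <- missing | (!is.na(da) & if (strict) da > threshold
                    else da >= threshold)
  out <- data.frame(spot_id = spots, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[[paste0("rel_", conds[1L])]] <- as.numeric(relMat[, 1L])
  out[[paste0("rel_", conds[2L])]] <- as.numeric(relMat[, 2L])
  out$da <- as.numeric(da)
  out$direction <- as.character(direction)
  out$significant <- as.logical(sig)
  out$missing_data <- as.logical(missing)
  out
}
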