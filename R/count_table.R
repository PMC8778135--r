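#' Construct a validated taxa-by-samples count table
#'
#' A count table is an integer matrix with taxa as rows and samples as
#' columns, the object every downstream stage consumes. The constructor
#' enforces the invariants the statistical machinery relies on: unique
#' identifiers, non-negative integral entries, at least two samples.
#'
#' @param counts numeric matrix (taxa x samples) with row and column names.
#' @return a `count_table`: an integer matrix of class `count_table`.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_mc("count table must carry taxon (row) and sample (column) names",
             "mc_validation_error")
  if (anyDuplicated(rownames(counts)))
    abort_mc("duplicate taxon identifiers in count table", "mc_validation_error")
  if (anyDuplicated(colnames(counts)))
    abort_mc("duplicate sample identifiers in count table", "mc_validation_error")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    abort_mc("count table needs at least 1 taxon and 2 samples", "mc_validation_error")
  if (!is.numeric(counts) || anyNA(counts) || any(!is.finite(counts)))
    abort_mc("count table entries must be finite numbers", "mc_validation_error")
  if (any(counts < 0))
    abort_mc("negative counts are not allowed", "mc_validation_error")
  if (any(abs(counts - round(counts)) > 1e-8))
    abort_mc("fractional counts are not allowed; counts must be integers",
             "mc_validation_error")
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(counts))
  counts
}

#' Read a count table from TSV
#'
#' @param path TSV file with a header row and identifiers in the first column.
#' @param orientation `"taxa_rows"` (default) if rows are taxa,
#'   `"samples_rows"` if rows are samples; the returned table is always
#'   taxa x samples.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character")
  ids <- raw[[1L]]
  body <- raw[-1L]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort_mc(sprintf("non-numeric count '%s' at row '%s', column '%s' in %s",
                     as.matrix(body)[bad[1L, , drop = FALSE]],
                     ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]], path),
             "mc_parse_error")
  rownames(num) <- ids
  if (orientation == "samples_rows") num <- t(num)
  count_table(num)
}

#' Write a count table to TSV (taxa as rows)
#' @param table a [count_table()].
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(taxon_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' Expects a `taxon_id` first column followed by rank columns
#' (kingdom ... genus order); empty cells mark missing ranks.
#'
#' @param path TSV path.
#' @return data.frame with rownames = taxon ids and one column per rank.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (anyDuplicated(tx[[1L]]))
    abort_mc("duplicate taxon identifiers in taxonomy", "mc_validation_error")
  if (ncol(tx) - 1L > 7L)
    abort_mc("taxonomy lineages cannot exceed 7 ranks", "mc_validation_error")
  rownames(tx) <- tx[[1L]]
  tx[-1L]
}

#' Write a taxonomy table to TSV
#' @param taxonomy data.frame of rank columns, rownames = taxon ids.
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- data.frame(taxon_id = rownames(taxonomy), taxonomy, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
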