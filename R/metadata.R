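#' Construct a validated sample metadata frame
#'
#' Per-sample variables with declared types, a designated target (grouping)
#' variable and an optional subgroup variable. Categorical variables keep
#' their levels in first-appearance order so design matrices are reproducible
#' without hidden alphabetical re-ordering.
#'
#' @param data data.frame of variables, one row per sample.
#' @param sample_ids character vector of unique sample identifiers.
#' @param schema named character vector mapping variable name to
#'   `"numeric"` or `"categorical"`; variables absent from the schema keep
#'   their column type (character/factor become categorical).
#' @param target name of the target grouping variable (>= 2 levels).
#' @param subgroup optional name of a subgroup variable.
#' @return a `metadata_frame`: a data.frame with rownames = sample ids and
#'   attributes `target` and `subgroup`.
#' @export
metadata_frame <- function(data, sample_ids, schema = NULL, target, subgroup = NULL) {
  if (anyDuplicated(sample_ids))
    abort_mc("duplicate sample identifiers in metadata", "mc_validation_error")
  if (length(sample_ids) != nrow(data))
    abort_mc("sample_ids length must match metadata rows", "mc_validation_error")
  if (!target %in% names(data))
    abort_mc(sprintf("target variable '%s' absent from metadata", target),
             "mc_config_error")
  if (!is.null(subgroup) && !subgroup %in% names(data))
    abort_mc(sprintf("subgroup variable '%s' absent from metadata", subgroup),
             "mc_config_error")
  for (v in names(data)) {
    ty <- if (!is.null(schema) && v %in% names(schema)) schema[[v]]
          else if (is.numeric(data[[v]])) "numeric" else "categorical"
    if (ty == "numeric") {
      x <- data[[v]]
      if (!is.numeric(x)) {
        xs <- suppressWarnings(as.numeric(as.character(x)))
        if (anyNA(xs) && !anyNA(x))
          abort_mc(sprintf("variable '%s' declared numeric but has non-numeric entry '%s'",
                           v, as.character(x)[which(is.na(xs))[1L]]),
                   "mc_parse_error")
        x <- xs
      }
      data[[v]] <- x
    } else if (ty == "categorical") {
      x <- as.character(data[[v]])
      data[[v]] <- factor(x, levels = unique(x))   # first-appearance order
    } else {
      abort_mc(sprintf("unknown type '%s' for variable '%s'", ty, v),
               "mc_config_error")
    }
  }
  if (nlevels(factor(data[[target]])) < 2L)
    abort_mc("target variable must have at least 2 levels", "mc_validation_error")
  rownames(data) <- sample_ids
  structure(data, target = target, subgroup = subgroup,
            class = c("metadata_frame", "data.frame"))
}

#' Read sample metadata from TSV
#'
#' @param path TSV keyed by a `sample_id` first column.
#' @param schema named character vector of variable -> `"numeric"` /
#'   `"categorical"`.
#' @param target target grouping variable name (must be in the header).
#' @param subgroup optional subgroup variable name.
#' @return a [metadata_frame()].
#' @export
read_metadata <- function(path, schema = NULL, target, subgroup = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!"sample_id" %in% names(raw)[1L])
    names(raw)[1L] <- "sample_id"
  metadata_frame(raw[-1L], sample_ids = raw[[1L]], schema = schema,
                 target = target, subgroup = subgroup)
}

#' Write sample metadata to TSV (sample_id first column)
#' @param meta a [metadata_frame()].
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  df <- data.frame(sample_id = rownames(meta), as.data.frame(meta),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

meta_target <- function(meta) attr(meta, "target")
meta_subgroup <- function(meta) attr(meta, "subgroup")

# Align a metadata frame with a count table's samples; error on mismatch.
align_meta <- function(table, meta) {
  missing <- setdiff(colnames(table), rownames(meta))
  if (length(missing) > 0L)
    abort_mc(paste0("samples absent from metadata: ",
                    paste(missing, collapse = ", ")), "mc_validation_error")
  out <- meta[colnames(table), , drop = FALSE]
  attr(out, "target") <- attr(meta, "target")
  attr(out, "subgroup") <- attr(meta, "subgroup")
  class(out) <- class(meta)
  out
}
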