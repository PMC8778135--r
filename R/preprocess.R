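#' Agglomerate a count table to a taxonomic rank
#'
#' Taxa sharing an identical lineage prefix up to `rank` are summed, the
#' counterpart of phyloseq's `tax_glom`. Taxa with a missing value at the
#' rank are grouped under a sentinel `unclassified-<parent>` bin so that
#' per-sample totals are conserved exactly.
#'
#' @param table a [count_table()].
#' @param taxonomy data.frame of rank columns, rownames = taxon ids
#'   (see [read_taxonomy()]).
#' @param rank name of a column of `taxonomy`.
#' @return a [count_table()] with one row per distinct lineage prefix.
#' @export
agglomerate <- function(table, taxonomy, rank) {
  if (!rank %in% names(taxonomy))
    abort_mc(sprintf("unknown rank '%s'; taxonomy has: %s", rank,
                     paste(names(taxonomy), collapse = ", ")),
             "mc_config_error")
  missing <- setdiff(rownames(table), rownames(taxonomy))
  if (length(missing) > 0L)
    abort_mc(paste0("taxa absent from taxonomy: ",
                    paste(utils::head(missing, 5L), collapse = ", ")),
             "mc_validation_error")
  ranks <- names(taxonomy)[seq_len(match(rank, names(taxonomy)))]
  lin <- taxonomy[rownames(table), ranks, drop = FALSE]
  at_rank <- as.character(lin[[rank]])
  label <- at_rank
  blank <- is.na(at_rank) | at_rank == ""
  if (any(blank)) {
    parent <- apply(lin[blank, , drop = FALSE], 1L, function(r) {
      r <- as.character(r)
      filled <- which(!is.na(r) & r != "")
      if (length(filled) == 0L) "root" else r[max(filled)]
    })
    label[blank] <- paste0("unclassified-", parent)
  }
  # group by the full lineage prefix, label rows by the rank value
  key <- apply(lin, 1L, function(r) paste(ifelse(is.na(r), "", r), collapse = ";"))
  key[blank] <- paste0("~", label[blank])
  agg <- rowsum(unclass(table) + 0L, group = key, reorder = FALSE)
  rownames(agg) <- make.unique(label[!duplicated(key)], sep = "/")
  count_table(agg)
}

#' Prevalence filter
#'
#' Keeps taxon `t` iff it is present (count > 0) in at least
#' `min_prevalence` of the samples, boundary inclusive.
#'
#' @param table a [count_table()].
#' @param min_prevalence fraction in (0, 1], default 0.10.
#' @return filtered [count_table()] with attribute `removed_taxa`.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.10) {
  if (min_prevalence <= 0 || min_prevalence > 1)
    abort_mc("min_prevalence must be in (0, 1]", "mc_config_error")
  prev <- rowMeans(unclass(table) > 0)
  keep <- prev >= min_prevalence - 1e-12
  if (!any(keep))
    abort_mc("prevalence filter removed every taxon; review the threshold",
             "mc_validation_error")
  out <- count_table(unclass(table)[keep, , drop = FALSE])
  attr(out, "removed_taxa") <- rownames(table)[!keep]
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants correcting for sequencing depth, computed
#' as the median across reference taxa of the ratio count / per-taxon
#' geometric mean, then standardized to geometric mean 1.
#' `median_of_ratios` uses only taxa with all-positive rows (the classic
#' bulk definition); `poscounts` computes each taxon's geometric mean over
#' its positive entries only and takes the per-sample median over taxa with
#' a positive count there — the variant suited to sparse microbiome tables,
#' which is the default.
#'
#' @param table a [count_table()].
#' @param method `"poscounts"` (default) or `"median_of_ratios"`.
#' @return named numeric vector of positive size factors (geometric mean 1)
#'   with attribute `method`.
#' @export
size_factors <- function(table, method = c("poscounts", "median_of_ratios")) {
  method <- match.arg(method)
  m <- unclass(table) + 0   # numeric
  if (any(colSums(m > 0) == 0L))
    abort_mc("every sample needs at least one positive count", "mc_validation_error")
  if (method == "median_of_ratios") {
    allpos <- rowSums(m > 0) == ncol(m)
    if (!any(allpos))
      abort_mc(paste("no taxon is positive in every sample;",
                     "use method = 'poscounts' for sparse tables"),
               "mc_validation_error")
    ref <- m[allpos, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
    s <- apply(ref / geo, 2L, stats::median)
  } else {
    geo <- apply(m, 1L, function(r) {
      pos <- r[r > 0]
      if (length(pos) == 0L) NA_real_ else exp(mean(log(pos)))
    })
    s <- vapply(seq_len(ncol(m)), function(j) {
      pos <- m[, j] > 0 & !is.na(geo)
      stats::median(m[pos, j] / geo[pos])
    }, numeric(1L))
  }
  s <- s / exp(mean(log(s)))
  names(s) <- colnames(m)
  structure(s, method = method)
}

#' Divide counts by per-sample size factors
#'
#' @param table a [count_table()].
#' @param s size factors from [size_factors()] (named by sample).
#' @return numeric matrix (taxa x samples) of normalized abundances.
#' @export
normalize_counts <- function(table, s) {
  if (!setequal(colnames(table), names(s)))
    abort_mc("size factors and count table cover different samples",
             "mc_validation_error")
  sweep(unclass(table) + 0, 2L, s[colnames(table)], `/`)
}
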