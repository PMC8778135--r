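#' Chao1 richness estimate (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1`/`F2` are the numbers of
#' singletons and doubletons. Defined on raw integer counts: singleton and
#' doubleton frequencies are meaningless after fractional normalization.
#'
#' @param counts non-negative integer vector for one sample.
#' @return Chao1 estimate, `>=` observed richness.
#' @export
chao1 <- function(counts) {
  check_alpha_input(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `-sum(p_i log p_i)` over positive proportions; natural log by default.
#'
#' @param counts non-negative vector (counts or normalized abundances).
#' @param base log base, `exp(1)` (default) or 2.
#' @return Shannon index, `>= 0`.
#' @export
shannon <- function(counts, base = exp(1)) {
  check_alpha_input(counts, integer_only = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Gini-Simpson diversity index
#'
#' `1 - sum(p_i^2)`, the probability two random reads come from different
#' taxa; in `[0, 1]`.
#'
#' @param counts non-negative vector (counts or normalized abundances).
#' @return Gini-Simpson index.
#' @export
simpson <- function(counts) {
  check_alpha_input(counts, integer_only = FALSE)
  p <- counts / sum(counts)
  1 - sum(p^2)
}

check_alpha_input <- function(counts, integer_only = TRUE) {
  if (any(counts < 0) || anyNA(counts))
    abort_mc("diversity input must be non-negative", "mc_validation_error")
  if (all(counts == 0))
    abort_mc("diversity undefined for an all-zero sample", "mc_validation_error")
  if (integer_only && any(abs(counts - round(counts)) > 1e-8))
    abort_mc("Chao1 requires integer counts", "mc_validation_error")
  invisible(TRUE)
}

#' Per-sample alpha diversity with a group test
#'
#' Chao1 is computed on the raw counts; Shannon and Simpson on the
#' (scale-invariant) proportions of the normalized table when provided.
#' Groups are compared with the Kruskal-Wallis rank test.
#'
#' @param table a [count_table()] (raw counts).
#' @param meta a [metadata_frame()]; grouping uses its target variable
#'   unless `group_var` overrides it.
#' @param normalized optional numeric matrix from [normalize_counts()]
#'   used for Shannon/Simpson.
#' @param group_var grouping variable name.
#' @return data.frame (metric, sample, value) with attribute `tests`:
#'   per-metric Kruskal-Wallis H and p.
#' @export
alpha_diversity <- function(table, meta, normalized = NULL, group_var = NULL) {
  meta <- align_meta(table, meta)
  group_var <- group_var %||% meta_target(meta)
  ab <- if (is.null(normalized)) unclass(table) + 0 else normalized[, colnames(table)]
  res <- data.frame(
    sample = rep(colnames(table), 3L),
    metric = rep(c("chao1", "shannon", "simpson"), each = ncol(table)),
    value = c(apply(unclass(table), 2L, chao1),
              apply(ab, 2L, shannon),
              apply(ab, 2L, simpson)))
  groups <- meta[[group_var]]
  tests <- do.call(rbind, lapply(split(res, res$metric), function(d) {
    ht <- alpha_group_test(stats::setNames(d$value, d$sample),
                           stats::setNames(groups, rownames(meta)))
    data.frame(metric = d$metric[1L], H = ht[["H"]], p = ht[["p"]])
  }))
  rownames(tests) <- NULL
  attr(res, "tests") <- tests
  res
}

#' Kruskal-Wallis group test for an alpha-diversity metric
#'
#' Rank-based H statistic with tie correction, chi-squared p-value on
#' (g - 1) degrees of freedom.
#'
#' @param values named numeric vector, one value per sample.
#' @param groups named group labels over the same samples.
#' @return c(H = statistic, p = p-value).
#' @export
alpha_group_test <- function(values, groups) {
  groups <- groups[names(values)]
  g <- factor(as.character(groups))
  if (nlevels(g) < 2L)
    abort_mc("group test needs at least 2 groups", "mc_validation_error")
  kt <- stats::kruskal.test(values, g)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}
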