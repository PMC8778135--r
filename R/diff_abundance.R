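design_matrix <- function(meta, terms) {
  df <- as.data.frame(meta)
  if (length(terms) == 0L) return(stats::model.matrix(~1, data = df))
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(form, data = df)
}

# Family selection by BIC on the REDUCED design + same-family full fit +
# LRT, with the non-convergence cascade: if the selected family cannot fit
# the full design, fall to the next-best converged family. Selecting on the
# design that excludes the tested term keeps the family choice independent
# of that term under the null, so the chi-squared reference stays honest;
# selecting on the full model couples the two (a family wins BIC exactly
# when the target explains extra structure, e.g. the zero pattern) and
# inflates the type-I error of the subsequent LRT.
taxon_lrt <- function(y, X_full, X_red, offset, families = glm_families) {
  sel <- select_distribution(y, X_red, offset, families = families)
  fits <- sel$fits
  ok <- names(fits)[vapply(fits, function(f) f$converged && is.finite(f$bic),
                           logical(1L))]
  order_bic <- ok[order(vapply(fits[ok], function(f) f$bic, numeric(1L)))]
  for (fam in order_bic) {
    full <- fit_taxon_glm(y, X_full, offset, fam)
    if (full$converged) {
      lrt <- lrt_compare(full, fits[[fam]])
      return(list(family = fam, full = full, reduced = fits[[fam]],
                  statistic = lrt[["statistic"]], df = lrt[["df"]],
                  p = lrt[["p"]],
                  cascaded = fam != sel$family))
    }
  }
  abort_mc("no family converged on both the full and reduced designs",
           "mc_fit_error")
}

#' Differential abundance under a competing-models suite
#'
#' Per taxon: selects the count family by BIC on the full design of the
#' requested mode, refits the nested design in the same family, and tests
#' the target with a likelihood-ratio test; p-values are
#' Benjamini-Hochberg-adjusted across taxa within the mode.
#' \itemize{
#'   \item mode `"IBDCC"`: full = target + covariates + confounders,
#'     reduced = covariates + confounders.
#'   \item mode `"IBD"`: full = target only, reduced = intercept.
#' }
#' With empty covariate and confounder sets the IBDCC mode degenerates
#' exactly to the IBD mode.
#'
#' @param table prevalence-filtered, agglomerated [count_table()].
#' @param meta a [metadata_frame()].
#' @param target target variable; defaults to the frame's target.
#' @param covariates,confounders variable names entering the adjusted model.
#' @param s size factors ([size_factors()]); `log(s)` is the model offset.
#' @param mode `"IBDCC"` or `"IBD"`.
#' @param alpha significance threshold on adjusted p-values.
#' @param families candidate count families.
#' @return data.frame (taxon, family, statistic, df, p, adj_p, significant,
#'   model) with attribute `skipped` (taxon, reason).
#' @export
run_model_suite <- function(table, meta, target = NULL,
                            covariates = character(), confounders = character(),
                            s = NULL, mode = c("IBDCC", "IBD"),
                            alpha = 0.05, families = glm_families) {
  mode <- match.arg(mode)
  meta <- align_meta(table, meta)
  target <- target %||% meta_target(meta)
  s <- s %||% stats::setNames(rep(1, ncol(table)), colnames(table))
  offset <- log(s[colnames(table)])
  vars <- if (mode == "IBDCC") unique(c(covariates, confounders)) else character()
  X_full <- design_matrix(meta, c(target, vars))
  X_red <- design_matrix(meta, vars)

  rows <- list(); skipped <- list()
  for (t in rownames(table)) {
    y <- unclass(table)[t, ]
    res <- tryCatch(taxon_lrt(y, X_full, X_red, offset, families),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[t]] <- conditionMessage(res)
      next
    }
    rows[[t]] <- data.frame(taxon = t, family = res$family,
                            statistic = res$statistic, df = res$df,
                            p = res$p, cascaded = res$cascaded)
  }
  if (length(rows) == 0L)
    abort_mc("every taxon was skipped; no differential-abundance result",
             "mc_fit_error")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < alpha
  out$model <- mode
  attr(out, "skipped") <- if (length(skipped))
    data.frame(taxon = names(skipped), reason = unlist(skipped)) else
    data.frame(taxon = character(), reason = character())
  attr(out, "terms") <- list(target = target, covariates = covariates,
                             confounders = confounders)
  out
}

#' Identify taxa whose significance depends on the model
#'
#' Partitions taxa into three disjoint sets by comparing significance flags
#' of the unadjusted (`IBD`) and adjusted (`IBDCC`) model runs: significant
#' under both, only under IBD, or only under IBDCC. The single-model sets
#' are the "non-overlapping" taxa whose association with the target is
#' candidate-explained by covariates/confounders (or masked by them).
#'
#' @param ibd,ibdcc results of [run_model_suite()] over the same taxa.
#' @return list of class `nof_report`: `both`, `ibd_only`, `ibdcc_only`.
#' @export
identify_nofs <- function(ibd, ibdcc) {
  if (!setequal(ibd$taxon, ibdcc$taxon))
    abort_mc("the two result sets cover different taxa", "mc_validation_error")
  sig_ibd <- ibd$taxon[ibd$significant]
  sig_cc <- ibdcc$taxon[ibdcc$significant]
  structure(list(both = sort(intersect(sig_ibd, sig_cc)),
                 ibd_only = sort(setdiff(sig_ibd, sig_cc)),
                 ibdcc_only = sort(setdiff(sig_cc, sig_ibd))),
            class = "nof_report")
}

#' Attribute a model-dependent taxon to single variables
#'
#' Two complementary probes of which variable drives a taxon's
#' model-dependent significance:
#' \itemize{
#'   \item approach 1: for each variable `v`, LRT of the target in
#'     `target + v` vs `v` — does adding `v` alone kill the target's
#'     significance?
#'   \item approach 2: for each `v`, LRT of the target in
#'     `target + (all variables except v)` vs `(all except v)` — does
#'     removing `v` from the adjusted model restore it?
#' }
#' A variable is attributed when approach-1 p >= `alpha` AND approach-2
#' p < `alpha`; all p-values are reported regardless.
#'
#' @param taxon taxon identifier (a row of `table`).
#' @param table a [count_table()].
#' @param meta a [metadata_frame()].
#' @param target target variable; defaults to the frame's target.
#' @param variables covariates union confounders to probe.
#' @param s size factors.
#' @param alpha threshold (default 0.05).
#' @param families candidate count families.
#' @return data.frame: variable, family per approach, approach-1 and
#'   approach-2 p, attributed flag.
#' @export
attribute_nof <- function(taxon, table, meta, target = NULL,
                          variables, s = NULL, alpha = 0.05,
                          families = glm_families) {
  meta <- align_meta(table, meta)
  target <- target %||% meta_target(meta)
  if (!taxon %in% rownames(table))
    abort_mc(sprintf("taxon '%s' absent from table", taxon), "mc_validation_error")
  s <- s %||% stats::setNames(rep(1, ncol(table)), colnames(table))
  offset <- log(s[colnames(table)])
  y <- unclass(table)[taxon, ]
  if (length(variables) == 0L)
    return(data.frame(variable = character(), p_approach1 = numeric(),
                      p_approach2 = numeric(), attributed = logical()))
  one <- function(full_terms, red_terms) {
    res <- tryCatch(
      taxon_lrt(y, design_matrix(meta, full_terms),
                design_matrix(meta, red_terms), offset, families),
      error = function(e) NULL)
    if (is.null(res)) c(p = NA_real_) else c(p = res$p)
  }
  rows <- lapply(variables, function(v) {
    p1 <- one(c(target, v), v)[["p"]]
    rest <- setdiff(variables, v)
    p2 <- if (length(rest) == 0L) one(target, character())[["p"]]
          else one(c(target, rest), rest)[["p"]]
    data.frame(variable = v, p_approach1 = p1, p_approach2 = p2)
  })
  out <- do.call(rbind, rows)
  out$attributed <- !is.na(out$p_approach1) & !is.na(out$p_approach2) &
    out$p_approach1 >= alpha & out$p_approach2 < alpha
  attr(out, "taxon") <- taxon
  out
}

#' Rerun the adjusted analysis with a subgroup as the target
#'
#' Identical machinery with a multi-level subgroup (e.g. disease extent or
#' behaviour classes) contrasted against a control level: re-screens
#' variable imbalance, optionally re-selects covariates from supplied
#' distance matrices, and runs both model suites plus the set comparison.
#' Subgroup levels with fewer than 2 samples are retained with a warning.
#' Taxa all-zero within the retained samples are dropped with a note
#' rather than failing.
#'
#' @param table a [count_table()].
#' @param meta a [metadata_frame()] with a subgroup variable.
#' @param subgroup subgroup variable name; defaults to the frame's.
#' @param control_level reference level (healthy-control analogue).
#' @param candidates candidate lifestyle/diet variables.
#' @param s size factors for the full sample set.
#' @param distances optional named list of [distance_matrix()] for
#'   covariate re-selection (subset to the retained samples).
#' @param levels subgroup levels to analyse; default all.
#' @param alpha significance threshold.
#' @param n_perm,seed PERMANOVA settings for re-selection.
#' @param families candidate count families.
#' @return list: `screen`, `selection` (or NULL), `covariates`,
#'   `confounders`, `ibd`, `ibdcc`, `nofs`, `dropped_taxa`, `samples`.
#' @export
subgroup_analysis <- function(table, meta, subgroup = NULL, control_level,
                              candidates, s = NULL, distances = NULL,
                              levels = NULL, alpha = 0.05, n_perm = 999,
                              seed = 1L, families = glm_families) {
  meta <- align_meta(table, meta)
  subgroup <- subgroup %||% meta_subgroup(meta)
  if (is.null(subgroup))
    abort_mc("no subgroup variable available", "mc_config_error")
  sub <- as.character(meta[[subgroup]])
  levels <- levels %||% unique(c(control_level, sub))
  if (!control_level %in% sub)
    abort_mc(sprintf("control level '%s' absent from '%s'", control_level,
                     subgroup), "mc_config_error")
  keep <- sub %in% levels
  small <- names(which(table(sub[keep]) < 2L))
  if (length(small) > 0L)
    warning(sprintf("subgroup level(s) with < 2 samples retained: %s",
                    paste(small, collapse = ", ")))
  ids <- colnames(table)[keep]
  tab2 <- unclass(table)[, ids, drop = FALSE]
  nonzero <- rowSums(tab2) > 0
  dropped <- rownames(tab2)[!nonzero]
  tab2 <- count_table(tab2[nonzero, , drop = FALSE])
  meta2 <- as.data.frame(meta)[ids, , drop = FALSE]
  lev_order <- c(control_level, setdiff(levels, control_level))
  meta2[[subgroup]] <- factor(as.character(meta2[[subgroup]]),
                              levels = lev_order)
  meta2 <- metadata_frame(meta2, sample_ids = ids, target = subgroup)
  s2 <- if (is.null(s)) NULL else s[ids]

  screen <- unbalance_screen(meta2, target = subgroup, variables = candidates,
                             alpha = alpha, seed = child_seed(seed, "screen"))
  confounders <- screen$variable[screen$confounder]
  selection <- NULL
  covariates <- character()
  if (!is.null(distances)) {
    d2 <- lapply(distances, function(d) {
      distance_matrix(as.matrix(d)[ids, ids], metric = attr(d, "metric") %||% "unknown")
    })
    selection <- stepwise_covariate_selection(d2, meta2, candidates,
                                              target = subgroup, alpha = alpha,
                                              n_perm = n_perm,
                                              seed = child_seed(seed, "select"))
    covariates <- selection$covariates
  }
  ibd <- run_model_suite(tab2, meta2, target = subgroup, s = s2, mode = "IBD",
                         alpha = alpha, families = families)
  ibdcc <- run_model_suite(tab2, meta2, target = subgroup,
                           covariates = covariates, confounders = confounders,
                           s = s2, mode = "IBDCC", alpha = alpha,
                           families = families)
  list(screen = screen, selection = selection, covariates = covariates,
       confounders = confounders, ibd = ibd, ibdcc = ibdcc,
       nofs = identify_nofs(ibd, ibdcc), dropped_taxa = dropped,
       samples = ids)
}
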