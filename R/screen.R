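#' Screen variables for group imbalance (potential confounders)
#'
#' Numeric variables are tested across target levels with the
#' Kruskal-Wallis rank test; categorical variables with Fisher's exact test
#' on the contingency table (exact where feasible, seeded Monte-Carlo
#' fallback for large tables, flagged in the report). Variables with
#' p < `alpha` are flagged as potential confounders.
#'
#' @param meta a [metadata_frame()].
#' @param target target variable name; defaults to the frame's target.
#' @param variables variables to screen; default all except target and
#'   subgroup.
#' @param alpha significance threshold (default 0.05).
#' @param mc_cutoff cell-count product above which Fisher's test falls back
#'   to Monte-Carlo.
#' @param seed seed for the Monte-Carlo fallback.
#' @return data.frame: variable, test, statistic, p, confounder flag.
#' @export
unbalance_screen <- function(meta, target = NULL, variables = NULL,
                             alpha = 0.05, mc_cutoff = 1e7, seed = 1L) {
  target <- target %||% meta_target(meta)
  g <- factor(meta[[target]])
  if (nlevels(g) < 2L)
    abort_mc("target must have >= 2 levels", "mc_validation_error")
  variables <- variables %||%
    setdiff(names(meta), c(target, meta_subgroup(meta)))
  rows <- lapply(variables, function(v) {
    x <- meta[[v]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning(sprintf("variable '%s' is constant; skipped", v))
      return(NULL)
    }
    if (is.numeric(x)) {
      kt <- stats::kruskal.test(x, g)
      data.frame(variable = v, test = "kruskal_wallis",
                 statistic = unname(kt$statistic), p = unname(kt$p.value),
                 monte_carlo = FALSE)
    } else {
      tab <- table(factor(x), g)
      mc <- prod(dim(tab)) > 6L && sum(tab)^2 * prod(dim(tab)) > mc_cutoff
      ft <- if (mc) {
        old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
        set.seed(child_seed(seed, v))
        stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)
      } else {
        stats::fisher.test(tab, workspace = 2e7)
      }
      data.frame(variable = v, test = "fisher_exact", statistic = NA_real_,
                 p = unname(ft$p.value), monte_carlo = mc)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(), test = character(),
                      statistic = numeric(), p = numeric(),
                      monte_carlo = logical())
  out$confounder <- out$p < alpha
  attr(out, "alpha") <- alpha
  out
}

# Hat matrix of a design, using only linearly independent columns.
hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Marginal-effect PERMANOVA
#'
#' Permutational multivariate ANOVA on a distance matrix, testing each
#' model term's marginal contribution given all others. The squared
#' distances are Gower-centered (`G = C (-D^2/2) C`); a term's marginal sum
#' of squares is `tr(H_full G) - tr(H_-t G)` where `H` are hat matrices of
#' the model with and without the term; the pseudo-F compares it with the
#' full-model residual. P-values come from whole-row permutations of the
#' distance matrix under a seeded RNG, with the add-one estimator
#' `(1 + #{F* >= F}) / (1 + n_perm)` so they are never exactly zero.
#'
#' @param d a [distance_matrix()] (or symmetric matrix with sample names).
#' @param meta a [metadata_frame()] covering the samples of `d`.
#' @param terms character vector of metadata variables to test.
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param permutations optional integer matrix (one permutation per row) to
#'   use instead of random draws, e.g. the exhaustive relabelling set.
#' @return data.frame of per-term df, SS, pseudo-F and p, with residual and
#'   total rows; attributes `n_perm` and `seed`.
#' @export
permanova_marginal <- function(d, meta, terms, n_perm = 9999, seed = 1L,
                               permutations = NULL) {
  d <- as.matrix(d)
  samples <- rownames(d)
  meta_df <- as.data.frame(meta)[samples, , drop = FALSE]
  missing <- setdiff(terms, names(meta_df))
  if (length(missing) > 0L)
    abort_mc(paste0("terms absent from metadata: ",
                    paste(missing, collapse = ", ")), "mc_config_error")
  n <- nrow(d)
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(form, data = meta_df)
  if (nrow(X) < n)
    abort_mc("missing values in model terms", "mc_validation_error")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    abort_mc(paste0("rank-deficient design; aliased columns: ",
                    paste(aliased, collapse = ", ")), "mc_validation_error")
  }
  if (n < ncol(X) + 2L)
    abort_mc("too few samples for the requested model", "mc_validation_error")

  G <- gower_center(d)
  assign_idx <- attr(X, "assign")
  H_full <- hat_matrix(X)
  H_drop <- lapply(seq_along(terms), function(k) {
    keep <- assign_idx != k
    hat_matrix(X[, keep, drop = FALSE])
  })
  df_t <- vapply(seq_along(terms), function(k) sum(assign_idx == k), integer(1L))
  df_res <- n - ncol(X)

  ss_stats <- function(Gp) {
    ss_full <- sum(H_full * Gp)
    ss_res <- sum(diag(Gp)) - ss_full
    ss_t <- vapply(seq_along(terms), function(k)
      ss_full - sum(H_drop[[k]] * Gp), numeric(1L))
    list(ss_t = ss_t, ss_res = ss_res)
  }
  obs <- ss_stats(G)
  f_obs <- (obs$ss_t / df_t) / (obs$ss_res / df_res)

  if (is.null(permutations)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    permutations <- t(replicate(n_perm, sample.int(n)))
  }
  n_perm_eff <- nrow(permutations)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm_eff)) {
    perm <- permutations[b, ]
    st <- ss_stats(G[perm, perm])
    f_b <- (st$ss_t / df_t) / (st$ss_res / df_res)
    exceed <- exceed + (f_b >= f_obs - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm_eff)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_t, df_res, n - 1L),
    SS = c(obs$ss_t, obs$ss_res, sum(diag(G))),
    pseudo_F = c(f_obs, NA, NA),
    p = c(p, NA, NA))
  attr(out, "n_perm") <- n_perm_eff
  attr(out, "seed") <- seed
  out
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a); cm <- colMeans(a); gm <- mean(a)
  sweep(sweep(a, 1L, rm), 2L, cm) + gm
}

#' Covariate selection by per-metric backward elimination
#'
#' For each beta-diversity metric, starts from the model
#' `target + candidates` and repeatedly removes the non-target term with
#' the largest marginal PERMANOVA p-value until every remaining non-target
#' term is significant at `alpha` (the target is never eliminated). Ties in
#' the largest p are broken by dropping the term appearing later in the
#' candidate order. Covariates are the union over metrics of surviving
#' non-target terms. The full elimination trace is retained so the
#' automated procedure can be audited like a manual one.
#'
#' @param distances named list of [distance_matrix()] objects, one per metric.
#' @param meta a [metadata_frame()].
#' @param candidates candidate variable names (target excluded).
#' @param target target variable; defaults to the frame's target.
#' @param alpha retention threshold (default 0.05).
#' @param n_perm permutations per PERMANOVA (default 9999).
#' @param seed seed; a child seed is derived per metric.
#' @return list: `covariates` (union), `by_metric` (surviving terms per
#'   metric), `table` (term x metric final p-values, Table-1 shaped),
#'   `target_p` (target p per metric), `trace` (elimination records).
#' @export
stepwise_covariate_selection <- function(distances, meta, candidates,
                                         target = NULL, alpha = 0.05,
                                         n_perm = 9999, seed = 1L) {
  target <- target %||% meta_target(meta)
  if (target %in% candidates)
    abort_mc("candidates must exclude the target variable", "mc_config_error")
  by_metric <- list(); trace <- list(); target_p <- numeric()
  pmat <- matrix(NA_real_, length(candidates) + 1L, length(distances),
                 dimnames = list(c(target, candidates), names(distances)))
  for (m in names(distances)) {
    terms <- c(target, candidates)
    repeat {
      res <- permanova_marginal(distances[[m]], meta, terms,
                                n_perm = n_perm,
                                seed = child_seed(seed, m))
      pv <- stats::setNames(res$p[seq_along(terms)], terms)
      cand_p <- pv[setdiff(terms, target)]
      if (length(cand_p) == 0L || all(cand_p < alpha)) {
        pmat[names(pv), m] <- pv
        target_p[m] <- pv[[target]]
        by_metric[[m]] <- setdiff(terms, target)
        break
      }
      worst <- max(cand_p)
      drop_candidates <- names(cand_p)[cand_p >= worst - 1e-15]
      # tie-break: drop the term appearing later in the candidate order
      drop <- drop_candidates[which.max(match(drop_candidates, candidates))]
      trace[[length(trace) + 1L]] <- data.frame(
        metric = m, dropped = drop, p_at_removal = unname(cand_p[drop]))
      terms <- setdiff(terms, drop)
    }
  }
  list(covariates = sort(unique(unlist(by_metric))),
       by_metric = by_metric,
       table = pmat,
       target_p = target_p,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(metric = character(), dropped = character(),
                    p_at_removal = numeric()))
}
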