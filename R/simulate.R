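#' Configuration for a synthetic microbiome cohort
#'
#' Defines a cohort with the statistical structure the downstream analysis
#' assumes: a multi-level study group (healthy-control-like reference plus
#' disease groups, optionally split into subgroups), binary lifestyle/diet
#' variables whose prevalence may differ by group (planted imbalance =
#' potential confounding), age and gender, and overdispersed zero-inflated
#' taxon counts in which chosen taxa respond to the group, to single
#' variables, or to both. Defaults mirror a three-group 16S cohort:
#' 42 controls and 52 + 58 cases, subgroup splits 27/22/3 and 9/18/28,
#' ages 19-72, 16 binary questionnaire variables.
#'
#' @param groups named integer vector: samples per group level; first level
#'   is the control/reference.
#' @param subgroups optional named list: for each group, a named integer
#'   vector of subgroup sizes summing to the group size.
#' @param n_taxa number of taxa.
#' @param baseline_log_mean per-taxon baseline log mean count (length
#'   `n_taxa`), or `NULL` to draw once from Uniform(log 2, log 200).
#' @param dispersion per-taxon negative-binomial size parameter (> 0), or
#'   `NULL` to draw from Uniform(0.3, 3).
#' @param zero_inflation per-taxon structural-zero probability in `[0, 1]`,
#'   or `NULL` to draw from Uniform(0, 0.25). Scalar recycled.
#' @param zero_model `"zinb"` (mixture structural zeros) or `"hurdle"`
#'   (zero mass + zero-truncated counts).
#' @param variables named list: for each binary variable, a named numeric
#'   vector of per-group P(yes). Unequal entries plant group imbalance.
#'   Default: 16 questionnaire-style variables, balanced at 0.5.
#' @param effects data.frame with columns `taxon`, `variable`, `level`,
#'   `lfc`: log-fold-changes planted on taxa. For the group variable,
#'   `level` names the group the effect applies to; for binary variables
#'   `level` is ignored (effect active when the sample answers "yes").
#' @param age_mean,age_sd per-group mean/sd of age, truncated to `[19, 72]`.
#' @param library_meanlog,library_sdlog log-normal library-size (relative
#'   sequencing depth) parameters.
#' @param seed integer RNG seed; the full generated tuple is a
#'   deterministic function of the config.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(groups = c(HC = 42, CD = 52, UC = 58),
                             subgroups = list(
                               CD = c(B1 = 27, B2 = 22, B3 = 3),
                               UC = c(E1 = 9, E2 = 18, E3 = 28, UC = 3)),
                             n_taxa = 50,
                             baseline_log_mean = NULL,
                             dispersion = NULL,
                             zero_inflation = NULL,
                             zero_model = c("zinb", "hurdle"),
                             variables = default_variables(names(groups)),
                             effects = NULL,
                             age_mean = NULL, age_sd = 13,
                             library_meanlog = 0, library_sdlog = 0.35,
                             seed = 1L) {
  zero_model <- match.arg(zero_model)
  if (any(groups < 2L)) abort_mc("need >= 2 samples per group", "mc_config_error")
  # the default subgroup splits only apply to the default cohort sizes
  if (missing(subgroups) && !is.null(subgroups)) {
    ok <- vapply(names(subgroups), function(g)
      g %in% names(groups) && sum(subgroups[[g]]) == groups[[g]], logical(1L))
    subgroups <- subgroups[ok]
    if (length(subgroups) == 0L) subgroups <- NULL
  }
  if (n_taxa < 1L) abort_mc("n_taxa must be >= 1", "mc_config_error")
  if (!is.null(dispersion) && any(dispersion <= 0))
    abort_mc("dispersion must be > 0", "mc_config_error")
  if (!is.null(zero_inflation) &&
      (any(zero_inflation < 0) || any(zero_inflation > 1)))
    abort_mc("zero_inflation must be in [0, 1]", "mc_config_error")
  for (v in names(variables)) {
    p <- variables[[v]]
    if (any(p < 0 | p > 1))
      abort_mc(sprintf("P(yes) for variable '%s' outside [0, 1]", v),
               "mc_config_error")
    if (!all(names(groups) %in% names(p)))
      abort_mc(sprintf("variable '%s' lacks a P(yes) for every group", v),
               "mc_config_error")
  }
  if (is.null(age_mean)) age_mean <- stats::setNames(rep(45, length(groups)),
                                                     names(groups))
  structure(list(groups = groups, subgroups = subgroups, n_taxa = n_taxa,
                 baseline_log_mean = baseline_log_mean,
                 dispersion = dispersion, zero_inflation = zero_inflation,
                 zero_model = zero_model, variables = variables,
                 effects = effects, age_mean = age_mean, age_sd = age_sd,
                 library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default binary questionnaire variables (balanced across groups)
#' @param group_names group level names.
#' @return named list of per-group P(yes), all 0.5.
#' @export
default_variables <- function(group_names) {
  vars <- c("dairy", "fruit_veg", "cereals", "legumes", "bread", "yogurt",
            "meat", "fish", "eggs", "sweets", "coffee", "alcohol",
            "smoking", "physical_activity", "lost_5kg", "gained_5kg")
  stats::setNames(lapply(vars, function(v)
    stats::setNames(rep(0.5, length(group_names)), group_names)), vars)
}

#' Simulate a random rooted phylogeny for synthetic taxa
#'
#' Random bifurcating topology with exponential branch lengths; tip labels
#' match the generated taxon identifiers.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed RNG seed.
#' @return rooted `phylo` object.
#' @export
generate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2L) abort_mc("a tree needs at least 2 tips", "mc_config_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = TRUE, br = stats::rexp,
                     tip.label = taxon_ids(n_taxa))
  tree
}

taxon_ids <- function(n) sprintf("fam%03d", seq_len(n))

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# zero-truncated negative binomial draw by inverse cdf
rztnbinom <- function(n, mu, size) {
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, p0, 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws group labels, subgroups, per-group Bernoulli lifestyle variables,
#' truncated-normal ages, log-normal library sizes and zero-inflated
#' negative-binomial counts whose means multiply the library size by
#' `exp(baseline + planted effects)`. Every drawn parameter is recorded in
#' the returned ground-truth ledger, which downstream validation uses as
#' the oracle.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `counts` ([count_table()]), `metadata`
#'   ([metadata_frame()] with target `group`), `taxonomy` (data.frame),
#'   `tree` (`phylo`), `truth` (list).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  taxa <- taxon_ids(config$n_taxa)
  b0 <- config$baseline_log_mean %||% stats::runif(config$n_taxa, log(2), log(200))
  theta <- config$dispersion %||% stats::runif(config$n_taxa, 0.3, 3)
  pi0 <- config$zero_inflation %||% stats::runif(config$n_taxa, 0, 0.25)
  b0 <- rep_len(b0, config$n_taxa)
  theta <- rep_len(theta, config$n_taxa)
  pi0 <- rep_len(pi0, config$n_taxa)

  groups <- rep(names(config$groups), config$groups)
  n <- length(groups)
  sample_id <- sprintf("S%03d", seq_len(n))
  subgroup <- groups
  for (g in names(config$subgroups %||% list())) {
    sz <- config$subgroups[[g]]
    if (sum(sz) != config$groups[[g]])
      abort_mc(sprintf("subgroup sizes for '%s' do not sum to group size", g),
               "mc_config_error")
    subgroup[groups == g] <- rep(names(sz), sz)
  }

  # binary lifestyle/diet variables, per-group Bernoulli
  vars <- config$variables
  X <- if (length(vars) > 0L) {
    vapply(names(vars), function(v) {
      p <- vars[[v]][groups]
      ifelse(stats::rbinom(n, 1L, p) == 1L, "yes", "no")
    }, character(n))
  } else matrix(character(0L), nrow = n, ncol = 0L)
  age <- rtrunc_norm(n, config$age_mean[groups], config$age_sd, 19, 72)
  gender <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "F", "M")

  # planted effects -> per-taxon lfc matrices
  glev <- names(config$groups)
  group_lfc <- matrix(0, config$n_taxa, length(glev),
                      dimnames = list(taxa, glev))
  sublev <- unique(subgroup)
  sub_lfc <- matrix(0, config$n_taxa, length(sublev),
                    dimnames = list(taxa, sublev))
  var_lfc <- matrix(0, config$n_taxa, length(vars),
                    dimnames = list(taxa, names(vars)))
  for (i in seq_len(NROW(config$effects))) {
    e <- config$effects[i, ]
    if (!e$taxon %in% taxa)
      abort_mc(sprintf("effect references unknown taxon '%s'", e$taxon),
               "mc_config_error")
    if (e$variable == "group") {
      if (!e$level %in% glev)
        abort_mc(sprintf("effect references unknown group level '%s'", e$level),
                 "mc_config_error")
      group_lfc[e$taxon, e$level] <- e$lfc
    } else if (e$variable == "subgroup") {
      if (!e$level %in% sublev)
        abort_mc(sprintf("effect references unknown subgroup level '%s'", e$level),
                 "mc_config_error")
      sub_lfc[e$taxon, e$level] <- e$lfc
    } else {
      if (!e$variable %in% names(vars))
        abort_mc(sprintf("effect references unknown variable '%s'", e$variable),
                 "mc_config_error")
      var_lfc[e$taxon, e$variable] <- e$lfc
    }
  }

  libsize <- stats::rlnorm(n, config$library_meanlog, config$library_sdlog)
  yes <- (X == "yes") * 1L                             # n x n_vars
  eta <- matrix(b0, config$n_taxa, n) +
    group_lfc[, groups, drop = FALSE] +
    sub_lfc[, subgroup, drop = FALSE] +
    (if (length(vars) > 0L) var_lfc %*% t(yes) else 0)
  mu <- sweep(exp(eta), 2L, libsize, `*`)

  counts <- matrix(0L, config$n_taxa, n, dimnames = list(taxa, sample_id))
  for (t in seq_len(config$n_taxa)) {
    if (config$zero_model == "zinb") {
      y <- stats::rnbinom(n, mu = mu[t, ], size = theta[t])
      zero <- stats::rbinom(n, 1L, pi0[t]) == 1L
      y[zero] <- 0L
    } else {
      zero <- stats::rbinom(n, 1L, pi0[t]) == 1L
      y <- integer(n)
      if (any(!zero)) y[!zero] <- rztnbinom(sum(!zero), mu[t, !zero], theta[t])
    }
    counts[t, ] <- y
  }

  meta_df <- data.frame(group = groups, subgroup = subgroup,
                        age = age, gender = gender, X,
                        stringsAsFactors = FALSE, check.names = FALSE)
  meta <- metadata_frame(meta_df, sample_ids = sample_id,
                         target = "group", subgroup = "subgroup")

  phyla <- paste0("phy", (seq_len(config$n_taxa) - 1L) %% 4L + 1L)
  taxonomy <- data.frame(kingdom = "Bacteria", phylum = phyla,
                         class = paste0("cls_", phyla),
                         order = paste0("ord_", phyla),
                         family = taxa, row.names = taxa)
  tree <- if (config$n_taxa >= 2L)
    generate_tree(config$n_taxa, seed = child_seed(config$seed, "tree"))
  else NULL

  imbalance <- vapply(vars, function(p)
    max(p[glev]) - min(p[glev]) > 1e-12, logical(1L))
  truth <- list(baseline_log_mean = stats::setNames(b0, taxa),
                dispersion = stats::setNames(theta, taxa),
                zero_inflation = stats::setNames(pi0, taxa),
                zero_model = config$zero_model,
                group_lfc = group_lfc, subgroup_lfc = sub_lfc,
                var_lfc = var_lfc,
                variable_imbalance = imbalance,
                library_sizes = stats::setNames(libsize, sample_id),
                seed = config$seed)

  list(counts = count_table(counts), metadata = meta, taxonomy = taxonomy,
       tree = tree, truth = truth)
}

#' Write a generated cohort to plain-text files
#'
#' Writes `counts.tsv`, `metadata.tsv`, `taxonomy.tsv`, `tree.nwk` and
#' `truth.json` under `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  if (!is.null(cohort$tree))
    ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  truth <- cohort$truth
  truth$group_lfc <- as.data.frame(truth$group_lfc)
  truth$subgroup_lfc <- as.data.frame(truth$subgroup_lfc)
  truth$var_lfc <- as.data.frame(truth$var_lfc)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
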