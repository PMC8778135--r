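#' Assemble a validated pipeline run configuration
#'
#' Either `simulate` (a [synthetic_config()]) or `inputs` (paths to
#' counts/metadata and optional taxonomy/tree TSV/Newick files plus the
#' metadata schema and target) must be supplied. Defaults fix the analysis
#' conventions: family-rank agglomeration, 10% prevalence (inclusive),
#' poscounts size factors, four beta metrics, 9999 permutations,
#' alpha = 0.05.
#'
#' @param simulate optional [synthetic_config()].
#' @param inputs optional list: `counts`, `metadata`, `taxonomy`, `tree`
#'   paths, `schema`, `target`, `subgroup`, `orientation`.
#' @param rank agglomeration rank (NULL = no agglomeration).
#' @param min_prevalence prevalence threshold.
#' @param sf_method size-factor method.
#' @param metrics beta metrics to compute.
#' @param gunifrac_alpha generalized-UniFrac exponent.
#' @param candidates candidate variables for screening/selection; default
#'   every metadata variable except target and subgroup.
#' @param n_perm PERMANOVA permutations.
#' @param alpha significance threshold.
#' @param seed global seed, fanned out to per-stage child seeds.
#' @param out_dir output directory (NULL = nothing persisted).
#' @param subgroup_runs optional named list of subgroup analyses, each a
#'   list(`control_level`, `levels`).
#' @return a `run_config` list.
#' @export
run_config <- function(simulate = NULL, inputs = NULL, rank = "family",
                       min_prevalence = 0.10,
                       sf_method = "poscounts",
                       metrics = c("bray_curtis", "canberra",
                                   "unweighted_unifrac", "weighted_unifrac"),
                       gunifrac_alpha = 0.5, candidates = NULL,
                       n_perm = 9999, alpha = 0.05, seed = 1L,
                       out_dir = NULL, subgroup_runs = NULL) {
  if (is.null(simulate) && is.null(inputs))
    abort_mc("run_config needs either a simulation config or input paths",
             "mc_config_error")
  if (!is.null(simulate) && !inherits(simulate, "synthetic_config"))
    abort_mc("simulate must be a synthetic_config", "mc_config_error")
  structure(list(simulate = simulate, inputs = inputs, rank = rank,
                 min_prevalence = min_prevalence, sf_method = sf_method,
                 metrics = metrics, gunifrac_alpha = gunifrac_alpha,
                 candidates = candidates, n_perm = n_perm, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir,
                 subgroup_runs = subgroup_runs),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments;
#'   a `simulate:` block is passed to [synthetic_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$groups)) sim$groups <- unlist(sim$groups)
    if (!is.null(sim$subgroups)) sim$subgroups <- lapply(sim$subgroups, unlist)
    if (!is.null(sim$variables)) sim$variables <- lapply(sim$variables, unlist)
    if (!is.null(sim$effects)) sim$effects <- do.call(rbind, lapply(sim$effects, as.data.frame))
    y$simulate <- do.call(synthetic_config, sim)
  }
  if (!is.null(y$inputs$schema)) y$inputs$schema <- unlist(y$inputs$schema)
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full confounder-aware analysis pipeline
#'
#' Stages, in order: ingest or simulate; agglomerate + prevalence filter +
#' size factors; alpha diversity with group tests; beta distances
#' (UniFrac metrics are skipped with a warning when no tree is available);
#' variable imbalance screen (confounders); stepwise PERMANOVA covariate
#' selection; per-taxon differential abundance under the unadjusted and
#' adjusted models; model-dependent taxon identification and per-variable
#' attribution; optional subgroup re-analyses. All intermediates are plain
#' TSV/JSON when `out_dir` is set, and the whole run is deterministic given
#' the config seed.
#'
#' @param config a [run_config()].
#' @return a `run_report` list with every stage's result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  persist <- function(obj, name) {
    if (!is.null(out)) write_tsv(obj, file.path(out, name))
    invisible(obj)
  }

  # -- ingest ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    if (!is.null(out)) write_cohort(cohort, file.path(out, "cohort"))
    counts <- cohort$counts; meta <- cohort$metadata
    taxonomy <- cohort$taxonomy; tree <- cohort$tree
    truth <- cohort$truth
  } else {
    ins <- config$inputs
    counts <- read_count_table(ins$counts,
                               orientation = ins$orientation %||% "taxa_rows")
    meta <- read_metadata(ins$metadata, schema = ins$schema,
                          target = ins$target, subgroup = ins$subgroup)
    taxonomy <- if (!is.null(ins$taxonomy)) read_taxonomy(ins$taxonomy) else NULL
    tree <- if (!is.null(ins$tree)) read_tree(ins$tree) else NULL
    truth <- NULL
  }
  meta <- align_meta(counts, meta)
  target <- meta_target(meta)

  # -- preprocessing --------------------------------------------------
  raw <- counts
  if (!is.null(config$rank) && !is.null(taxonomy))
    counts <- agglomerate(counts, taxonomy, config$rank)
  counts <- prevalence_filter(counts, config$min_prevalence)
  s <- size_factors(counts, method = config$sf_method)
  norm <- normalize_counts(counts, s)
  persist(data.frame(sample_id = names(s), size_factor = as.numeric(s)),
          "size_factors.tsv")

  # -- alpha diversity ------------------------------------------------
  alpha_tab <- alpha_diversity(counts, meta, normalized = norm)
  persist(alpha_tab, "alpha.tsv")
  persist(attr(alpha_tab, "tests"), "alpha_tests.tsv")

  # -- beta diversity -------------------------------------------------
  distances <- list()
  # UniFrac needs every retained taxon as a tree tip; after agglomeration
  # to a coarser rank that mapping is gone, so fall back to the raw taxa.
  unifrac_tab <- if (!is.null(tree) &&
                     all(rownames(counts) %in% tree$tip.label)) counts else raw
  for (m in config$metrics) {
    needs_tree <- grepl("unifrac", m)
    if (needs_tree && is.null(tree)) {
      warning(sprintf("metric '%s' skipped: no tree supplied", m))
      next
    }
    x <- if (needs_tree) normalize_counts(unifrac_tab, size_factors(unifrac_tab, config$sf_method))
         else norm
    distances[[m]] <- beta_distance(x, metric = m, tree = tree,
                                    alpha = config$gunifrac_alpha)
    if (!is.null(out))
      utils::write.table(as.matrix(distances[[m]]),
                         file.path(out, paste0("beta_", m, ".tsv")),
                         sep = "\t", quote = FALSE)
  }

  # -- confounder screen + covariate selection ------------------------
  candidates <- config$candidates %||%
    setdiff(names(meta), c(target, meta_subgroup(meta)))
  screen <- unbalance_screen(meta, target = target, variables = candidates,
                             alpha = config$alpha,
                             seed = child_seed(config$seed, "screen"))
  persist(screen, "screen.tsv")
  confounders <- screen$variable[screen$confounder]
  selection <- NULL; covariates <- character()
  if (length(distances) > 0L) {
    selection <- stepwise_covariate_selection(
      distances, meta, candidates, target = target, alpha = config$alpha,
      n_perm = config$n_perm, seed = child_seed(config$seed, "select"))
    covariates <- selection$covariates
    if (!is.null(out))
      utils::write.table(selection$table, file.path(out, "covariate_table.tsv"),
                         sep = "\t", quote = FALSE)
  }

  # -- differential abundance -----------------------------------------
  ibd <- run_model_suite(counts, meta, target = target, s = s, mode = "IBD",
                         alpha = config$alpha)
  ibdcc <- run_model_suite(counts, meta, target = target,
                           covariates = covariates, confounders = confounders,
                           s = s, mode = "IBDCC", alpha = config$alpha)
  persist(ibd, "da_ibd.tsv"); persist(ibdcc, "da_ibdcc.tsv")
  nofs <- identify_nofs(ibd, ibdcc)

  attribution <- list()
  vars <- unique(c(covariates, confounders))
  for (t in c(nofs$ibd_only, nofs$ibdcc_only)) {
    attribution[[t]] <- attribute_nof(t, counts, meta, target = target,
                                      variables = vars, s = s,
                                      alpha = config$alpha)
  }
  if (!is.null(out)) {
    jsonlite::write_json(unclass(nofs), file.path(out, "nof_report.json"))
    if (length(attribution) > 0L) {
      att <- do.call(rbind, Map(function(t, d) cbind(taxon = t, d),
                                names(attribution), attribution))
      write_tsv(att, file.path(out, "attribution.tsv"))
    }
  }

  # -- subgroup re-analyses -------------------------------------------
  subgroups <- list()
  for (nm in names(config$subgroup_runs %||% list())) {
    sg <- config$subgroup_runs[[nm]]
    subgroups[[nm]] <- subgroup_analysis(
      counts, meta, control_level = sg$control_level,
      candidates = candidates, s = s, distances = distances,
      levels = sg$levels, alpha = config$alpha, n_perm = config$n_perm,
      seed = child_seed(config$seed, paste0("subgroup_", nm)))
  }

  report <- list(config = config, n_samples = ncol(counts),
                 n_taxa = nrow(counts), size_factors = s,
                 alpha = alpha_tab, alpha_tests = attr(alpha_tab, "tests"),
                 distances = distances, screen = screen,
                 confounders = confounders, selection = selection,
                 covariates = covariates, ibd = ibd, ibdcc = ibdcc,
                 nofs = nofs, attribution = attribution,
                 subgroups = subgroups, truth = truth)
  class(report) <- "run_report"
  if (!is.null(out)) {
    summary_json <- list(
      n_samples = ncol(counts), n_taxa = nrow(counts),
      alpha_tests = attr(alpha_tab, "tests"),
      confounders = confounders, covariates = covariates,
      n_significant_ibd = sum(ibd$significant),
      n_significant_ibdcc = sum(ibdcc$significant),
      nofs = unclass(nofs))
    jsonlite::write_json(summary_json, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
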