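confounded_cohort <- function(seed, n = 50L, n_taxa = 12L) {
  # one taxon driven only by an imbalanced diet variable, one by the group;
  # effect sizes sized so the induced marginal group effect is detectable
  # without the diet variable dominating the within-group variance
  eff <- rbind(
    data.frame(taxon = "fam001", variable = "cereals", level = NA, lfc = 1.2),
    data.frame(taxon = "fam002", variable = "group", level = "CD", lfc = 1.0),
    data.frame(taxon = "fam002", variable = "group", level = "UC", lfc = 1.0))
  vars <- default_variables(c("HC", "CD", "UC"))[c("cereals", "bread", "yogurt")]
  vars$cereals <- c(HC = 0.15, CD = 0.85, UC = 0.85)
  synthetic_config(groups = c(HC = n, CD = n, UC = n), n_taxa = n_taxa,
                   dispersion = 4, zero_inflation = 0.05,
                   variables = vars, effects = eff, seed = seed)
}

test_that("model suite flags a planted group effect under both models", {
  co <- generate_cohort(confounded_cohort(71L))
  tab <- prevalence_filter(co$counts, 0.10)
  s <- size_factors(tab)
  ibd <- run_model_suite(tab, co$metadata, s = s, mode = "IBD")
  ibdcc <- run_model_suite(tab, co$metadata,
                           covariates = c("age", "gender"),
                           confounders = "cereals", s = s, mode = "IBDCC")
  expect_true(ibd$significant[ibd$taxon == "fam002"])
  expect_true(ibdcc$significant[ibdcc$taxon == "fam002"])
  expect_true(all(ibd$adj_p >= ibd$p))
  expect_setequal(unique(ibd$family), intersect(unique(ibd$family),
                  c("poisson", "nb", "zinb", "hurdle")))
})

test_that("a diet-confounded taxon is model-dependent and attributed", {
  co <- generate_cohort(confounded_cohort(72L))
  tab <- prevalence_filter(co$counts, 0.10)
  s <- size_factors(tab)
  vars <- c("age", "gender", "cereals", "bread", "yogurt")
  ibd <- run_model_suite(tab, co$metadata, s = s, mode = "IBD")
  ibdcc <- run_model_suite(tab, co$metadata, covariates = vars, s = s,
                           mode = "IBDCC")
  nofs <- identify_nofs(ibd, ibdcc)
  expect_true("fam001" %in% nofs$ibd_only)
  att <- attribute_nof("fam001", tab, co$metadata, variables = vars, s = s)
  expect_true(att$attributed[att$variable == "cereals"])
  expect_lt(att$p_approach2[att$variable == "cereals"], 0.05)
  expect_gte(att$p_approach1[att$variable == "cereals"], 0.05)
})

test_that("a purely group-driven taxon attributes to no variable", {
  co <- generate_cohort(confounded_cohort(73L))
  tab <- prevalence_filter(co$counts, 0.10)
  s <- size_factors(tab)
  att <- attribute_nof("fam002", tab, co$metadata,
                       variables = c("bread", "yogurt"), s = s)
  expect_false(any(att$attributed))
  # empty variable set -> empty attribution table
  att0 <- attribute_nof("fam002", tab, co$metadata, variables = character(),
                        s = s)
  expect_equal(nrow(att0), 0L)
})

test_that("NOF sets are disjoint and follow the significance flags", {
  a <- data.frame(taxon = c("A", "B", "C"), significant = c(TRUE, TRUE, FALSE))
  b <- data.frame(taxon = c("A", "B", "C"), significant = c(FALSE, TRUE, FALSE))
  nofs <- identify_nofs(a, b)
  expect_equal(nofs$ibd_only, "A")
  expect_equal(nofs$both, "B")
  expect_length(nofs$ibdcc_only, 0L)
  expect_length(intersect(nofs$both, nofs$ibd_only), 0L)
  # identical flags -> both == all significant, NOF sets empty
  nofs2 <- identify_nofs(a, a)
  expect_setequal(nofs2$both, c("A", "B"))
  expect_length(nofs2$ibd_only, 0L)
  expect_error(identify_nofs(a, b[1:2, ]), "different taxa")
})

test_that("IBDCC with no covariates or confounders equals the IBD model", {
  co <- generate_cohort(confounded_cohort(74L, n = 25L, n_taxa = 8L))
  tab <- prevalence_filter(co$counts, 0.10)
  s <- size_factors(tab)
  ibd <- run_model_suite(tab, co$metadata, s = s, mode = "IBD")
  deg <- run_model_suite(tab, co$metadata, covariates = character(),
                         confounders = character(), s = s, mode = "IBDCC")
  expect_identical(ibd$p, deg$p)
  expect_identical(ibd$statistic, deg$statistic)
  expect_identical(ibd$family, deg$family)
})

test_that("skipped taxa are recorded instead of failing the suite", {
  co <- generate_cohort(confounded_cohort(75L, n = 25L, n_taxa = 8L))
  m <- unclass(co$counts)
  m["fam003", ] <- 0L   # would error in a direct fit; suite must skip it
  tab <- count_table(m)
  res <- run_model_suite(tab, co$metadata, mode = "IBD")
  sk <- attr(res, "skipped")
  expect_true("fam003" %in% sk$taxon)
  expect_false("fam003" %in% res$taxon)
})

test_that("subgroup analysis with the main grouping reproduces the main run", {
  co <- generate_cohort(confounded_cohort(76L, n = 25L, n_taxa = 8L))
  tab <- prevalence_filter(co$counts, 0.10)
  s <- size_factors(tab)
  main <- run_model_suite(tab, co$metadata, s = s, mode = "IBD")
  sub <- subgroup_analysis(tab, co$metadata, subgroup = "group",
                           control_level = "HC",
                           candidates = c("age", "cereals"), s = s)
  expect_equal(sub$ibd$p, main$p, tolerance = 1e-9)
})

test_that("a subgroup effect gradient is recovered in the level coefficients", {
  eff <- rbind(
    data.frame(taxon = "fam001", variable = "subgroup", level = "E1", lfc = 0.5),
    data.frame(taxon = "fam001", variable = "subgroup", level = "E2", lfc = 1.0),
    data.frame(taxon = "fam001", variable = "subgroup", level = "E3", lfc = 1.8))
  cfg <- synthetic_config(groups = c(HC = 40, UC = 45),
                          subgroups = list(UC = c(E1 = 15, E2 = 15, E3 = 15)),
                          n_taxa = 6, dispersion = 4, zero_inflation = 0.02,
                          variables = default_variables(c("HC", "UC"))[1:3],
                          effects = eff, seed = 77)
  co <- generate_cohort(cfg)
  tab <- prevalence_filter(co$counts, 0.10)
  s <- size_factors(tab)
  sub <- subgroup_analysis(tab, co$metadata, control_level = "HC",
                           candidates = c("age", "dairy"), s = s)
  expect_true(sub$ibdcc$significant[sub$ibdcc$taxon == "fam001"])
  # fitted level coefficients reproduce the planted ordering
  meta_ids <- sub$samples
  meta2 <- as.data.frame(co$metadata)[meta_ids, ]
  meta2$subgroup <- factor(meta2$subgroup, levels = c("HC", "E1", "E2", "E3"))
  X <- model.matrix(~subgroup, meta2)
  fit <- fit_taxon_glm(unclass(tab)["fam001", meta_ids], X,
                       offset = log(s[meta_ids]), family = "nb")
  cf <- fit$coef[c("subgroupE1", "subgroupE2", "subgroupE3")]
  expect_true(all(diff(cf) > 0))
  expect_true(all(cf > 0))
})

test_that("tiny subgroup levels warn but are retained", {
  cfg <- synthetic_config(groups = c(HC = 20, CD = 21),
                          subgroups = list(CD = c(B1 = 10, B2 = 10, B3 = 1)),
                          n_taxa = 5, seed = 78,
                          variables = default_variables(c("HC", "CD"))[1:2])
  co <- generate_cohort(cfg)
  tab <- prevalence_filter(co$counts, 0.10)
  expect_warning(
    sub <- subgroup_analysis(tab, co$metadata, control_level = "HC",
                             candidates = "dairy"),
    "< 2 samples")
  expect_true("B3" %in% co$metadata$subgroup[co$metadata$subgroup %in% "B3"])
  expect_s3_class(sub$ibdcc, "data.frame")
})
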