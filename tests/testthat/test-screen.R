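test_that("Fisher screen reproduces the hypergeometric enumeration", {
  # 2x2 table [[2,0],[0,2]]: two-sided exact p = 1/3
  meta <- metadata_frame(
    data.frame(group = c("A", "A", "B", "B"),
               v = c("yes", "yes", "no", "no")),
    sample_ids = sprintf("s%d", 1:4), target = "group")
  scr <- unbalance_screen(meta, variables = "v")
  expect_equal(scr$test, "fisher_exact")
  expect_equal(scr$p, 1 / 3, tolerance = 1e-12)
})

test_that("constant and degenerate variables are handled", {
  meta <- metadata_frame(
    data.frame(group = rep(c("A", "B"), each = 3),
               flat = rep("yes", 6)),
    sample_ids = sprintf("s%d", 1:6), target = "group")
  expect_warning(scr <- unbalance_screen(meta), "constant")
  expect_equal(nrow(scr), 0L)
  # identical numeric values across groups: all ties, KW p = 1 (degenerate)
  meta2 <- metadata_frame(
    data.frame(group = rep(c("A", "B"), each = 3),
               x = rep(c(1, 2, 3), 2)),
    sample_ids = sprintf("s%d", 1:6), target = "group")
  scr2 <- unbalance_screen(meta2)
  expect_equal(scr2$test, "kruskal_wallis")
  expect_gt(scr2$p, 0.9)
})

test_that("a planted imbalance is flagged with high power", {
  hits <- vapply(1:60, function(i) {
    co <- generate_cohort(synthetic_config(
      groups = c(HC = 50, CD = 50), n_taxa = 1, seed = 5000L + i,
      variables = list(dairy = c(HC = 0.2, CD = 0.8))))
    scr <- unbalance_screen(co$metadata, variables = "dairy")
    scr$confounder[1L]
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("single-binary-term PERMANOVA equals classical one-way ANOVA F", {
  set.seed(41)
  u <- c(1.2, 3.4, 0.8, 5.1, 4.4, 2.2)
  g <- rep(c("a", "b"), each = 3)
  d <- distance_matrix(as.matrix(dist(u)), "euclidean")
  rownames(d) <- colnames(d) <- sprintf("s%d", 1:6)
  meta <- metadata_frame(data.frame(group = g), sprintf("s%d", 1:6),
                         target = "group")
  res <- permanova_marginal(d, meta, "group", n_perm = 99, seed = 1)
  f_classic <- anova(lm(u ~ g))$`F value`[1L]
  expect_equal(res$pseudo_F[1L], f_classic, tolerance = 1e-10)
})

test_that("permutation p matches the exhaustive relabelling enumeration", {
  set.seed(42)
  u <- rnorm(6) + rep(c(0, 1.5), each = 3)
  ids <- sprintf("s%d", 1:6)
  d <- distance_matrix(`dimnames<-`(as.matrix(dist(u)), list(ids, ids)),
                       "euclidean")
  g <- rep(c("a", "b"), each = 3)
  meta <- metadata_frame(data.frame(group = g), ids, target = "group")
  # one permutation per distinct relabelling (choose(6,3) = 20)
  combos <- combn(6, 3)
  perms <- t(apply(combos, 2L, function(idx) c(idx, setdiff(1:6, idx))))
  res <- permanova_marginal(d, meta, "group", permutations = perms)
  # oracle: classical F recomputed per relabelling, add-one counting
  f_obs <- oracle_permanova_f(as.matrix(d), factor(g))
  f_perm <- apply(combos, 2L, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    oracle_permanova_f(as.matrix(d), factor(gg))
  })
  p_oracle <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + length(f_perm))
  expect_equal(res$p[1L], p_oracle, tolerance = 1e-12)
})

test_that("marginal SS and pseudo-F agree with vegan adonis2 by margin", {
  skip_if_not_installed("vegan")
  co <- generate_cohort(small_config(seed = 43L))
  s <- size_factors(co$counts)
  d <- beta_distance(normalize_counts(co$counts, s), "bray_curtis")
  meta <- co$metadata
  res <- permanova_marginal(d, meta, c("group", "age", "dairy"),
                            n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(as.matrix(d)) ~ group + age + dairy,
                        data = as.data.frame(meta), by = "margin",
                        permutations = 99)
  expect_equal(res$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(res$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(res$df[1:3], ref$Df[1:3])
})

test_that("PERMANOVA is seed-deterministic and add-one bounded", {
  co <- generate_cohort(small_config(seed = 44L))
  d <- beta_distance(normalize_counts(co$counts, size_factors(co$counts)),
                     "bray_curtis")
  r1 <- permanova_marginal(d, co$metadata, c("group", "age"),
                           n_perm = 199, seed = 9)
  r2 <- permanova_marginal(d, co$metadata, c("group", "age"),
                           n_perm = 199, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$p[1:2] >= 1 / 200))
})

test_that("aliased designs error naming the aliased columns", {
  co <- generate_cohort(small_config(seed = 45L))
  meta <- as.data.frame(co$metadata)
  meta$dup <- meta$age
  meta <- metadata_frame(meta, rownames(co$metadata), target = "group")
  d <- beta_distance(normalize_counts(co$counts, size_factors(co$counts)),
                     "bray_curtis")
  expect_error(permanova_marginal(d, meta, c("group", "age", "dup"),
                                  n_perm = 9, seed = 1),
               "aliased.*dup")
})

test_that("backward elimination keeps the target, unions over metrics", {
  # planted: 'dairy' shifts half the taxa -> should survive in >= 1 metric
  eff <- do.call(rbind, lapply(sprintf("fam%03d", 1:6), function(t)
    data.frame(taxon = t, variable = "dairy", level = NA, lfc = 1.5)))
  co <- generate_cohort(synthetic_config(
    groups = c(HC = 30, CD = 30), n_taxa = 12,
    variables = list(dairy = c(HC = 0.5, CD = 0.5),
                     bread = c(HC = 0.5, CD = 0.5)),
    effects = eff, seed = 46))
  s <- size_factors(co$counts)
  norm <- normalize_counts(co$counts, s)
  dists <- list(bray_curtis = beta_distance(norm, "bray_curtis"),
                canberra = beta_distance(norm, "canberra"))
  sel <- stepwise_covariate_selection(dists, co$metadata,
                                      candidates = c("dairy", "bread", "age"),
                                      n_perm = 199, seed = 5)
  expect_true("dairy" %in% sel$covariates)
  expect_false("group" %in% sel$covariates)
  expect_true(all(c("bray_curtis", "canberra") %in% names(sel$target_p)))
  # empty candidate set: no covariates, target p still reported
  sel0 <- stepwise_covariate_selection(dists, co$metadata,
                                       candidates = character(),
                                       n_perm = 99, seed = 5)
  expect_length(sel0$covariates, 0L)
  expect_true(all(sel0$target_p > 0 & sel0$target_p <= 1))
  expect_error(stepwise_covariate_selection(dists, co$metadata,
                                            candidates = c("group", "age"),
                                            n_perm = 99, seed = 5),
               "exclude the target")
})
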