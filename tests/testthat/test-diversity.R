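test_that("alpha estimators match hand-evaluated closed forms", {
  # chao1: no singletons -> observed richness; bias-corrected form otherwise
  expect_equal(chao1(c(5, 5, 5)), 3)
  expect_equal(chao1(c(1, 1, 2, 5, 9)), 5.5)   # 5 + 2*1/(2*2)
  expect_equal(chao1(1), 1)                     # F1=1 -> correction term 0
  expect_gte(chao1(c(1, 1, 1, 4)), 4)          # never below observed richness
  # shannon
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(rep(3, 4)), log(4))
  expect_equal(shannon(c(1, 3)), -(0.25 * log(0.25) + 0.75 * log(0.75)))
  expect_equal(shannon(c(1, 1, 1, 1), base = 2), 2)
  # simpson (Gini-Simpson)
  expect_equal(simpson(c(9)), 0)
  expect_equal(simpson(rep(2, 5)), 1 - 1 / 5)
  expect_equal(simpson(c(1, 3)), 0.375)
  # errors
  expect_error(chao1(c(0, 0)), "all-zero")
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(chao1(c(1.5, 2)), "integer")
})

test_that("alpha estimators agree with the vegan reference", {
  set.seed(10)
  for (i in 1:5) {
    y <- rpois(20, 3)
    if (all(y == 0)) next
    expect_equal(shannon(y), unname(vegan::diversity(y, "shannon")))
    expect_equal(simpson(y), unname(vegan::diversity(y, "simpson")))
    expect_equal(chao1(y), unname(vegan::estimateR(y)["S.chao1"]))
  }
})

test_that("Kruskal-Wallis group test matches the textbook rank formula", {
  v <- setNames(c(1, 2, 3, 10, 20, 30), sprintf("s%d", 1:6))
  g <- setNames(rep(c("a", "b"), each = 3), names(v))
  ht <- alpha_group_test(v, g)
  expect_equal(unname(ht["H"]), 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7,
               tolerance = 1e-12)
  expect_equal(unname(ht["p"]), pchisq(unname(ht["H"]), 1, lower.tail = FALSE))
  # rank invariance under sample reordering
  perm <- sample(names(v))
  ht2 <- alpha_group_test(v[perm], g[perm])
  expect_equal(ht, ht2)
  expect_error(alpha_group_test(v, setNames(rep("a", 6), names(v))),
               "2 groups")
})

test_that("alpha_diversity assembles per-sample values and group tests", {
  co <- generate_cohort(small_config(seed = 21L))
  s <- size_factors(co$counts)
  tab <- alpha_diversity(co$counts, co$metadata,
                         normalized = normalize_counts(co$counts, s))
  expect_setequal(unique(tab$metric), c("chao1", "shannon", "simpson"))
  tests <- attr(tab, "tests")
  expect_equal(nrow(tests), 3L)
  expect_true(all(tests$p >= 0 & tests$p <= 1))
})

test_that("abundance-based beta metrics match closed forms and stay bounded", {
  x <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(as.matrix(beta_distance(x, "bray_curtis"))["s1", "s2"], 1)
  m <- matrix(c(2, 2, 4, 1, 0, 8), 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  bc <- as.matrix(beta_distance(m, "bray_curtis"))["s1", "s2"]
  expect_equal(bc, (1 + 2 + 4) / (3 + 2 + 12))
  cb <- as.matrix(beta_distance(m, "canberra"))["s1", "s2"]
  expect_equal(cb, (1 / 3 + 2 / 2 + 4 / 12) / 3)
  # identical columns -> zero distance for every metric
  set.seed(30)
  co <- generate_cohort(small_config(seed = 30L, n_taxa = 8L))
  xx <- unclass(co$counts) + 0
  xx[, 2] <- xx[, 1]
  colnames(xx) <- colnames(co$counts)
  for (metric in c("bray_curtis", "canberra", "unweighted_unifrac",
                   "weighted_unifrac", "generalized_unifrac")) {
    d <- as.matrix(beta_distance(xx, metric, tree = co$tree))
    expect_equal(d[1, 2], 0, info = metric)
    expect_true(all(d >= 0) && all(abs(diag(d)) < 1e-12), info = metric)
    expect_equal(d, t(d), info = metric)
    if (metric %in% c("bray_curtis", "canberra", "unweighted_unifrac"))
      expect_true(all(d <= 1 + 1e-12), info = metric)
  }
})

test_that("UniFrac matches the per-branch brute-force oracle on small trees", {
  set.seed(31)
  for (rep in 1:5) {
    tr <- generate_tree(5, seed = 300 + rep)
    x <- matrix(rpois(10, 4), 5, 2,
                dimnames = list(tr$tip.label, c("s1", "s2")))
    x[1, 1] <- 0
    if (any(colSums(x) == 0)) next
    for (metric in c("unweighted_unifrac", "weighted_unifrac",
                     "generalized_unifrac")) {
      got <- as.matrix(beta_distance(x, metric, tree = tr, alpha = 0.5))[1, 2]
      key <- sub("_unifrac", "", metric)
      expect_equal(got, oracle_unifrac(tr, setNames(x[, 1], rownames(x)),
                                       setNames(x[, 2], rownames(x)),
                                       key, alpha = 0.5),
                   tolerance = 1e-12, info = metric)
    }
  }
})

test_that("samples on disjoint clades have unweighted UniFrac 1", {
  tr <- ape::read.tree(text = "((A:1,B:1):0,(C:1,D:1):0);")
  x <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  expect_equal(as.matrix(beta_distance(x, "unweighted_unifrac", tree = tr))[1, 2], 1)
})

test_that("generalized UniFrac at alpha 1 equals weighted-normalized", {
  co <- generate_cohort(small_config(seed = 33L, n_taxa = 10L))
  x <- unclass(co$counts) + 0
  dw <- as.matrix(beta_distance(x, "weighted_unifrac", tree = co$tree))
  dg <- as.matrix(beta_distance(x, "generalized_unifrac", tree = co$tree,
                                alpha = 1))
  expect_lt(max(abs(dw - dg)), 1e-10)
})

test_that("UniFrac is invariant to tip rotation and prunes extra tips", {
  co <- generate_cohort(small_config(seed = 34L, n_taxa = 6L))
  x <- unclass(co$counts) + 0
  tr <- co$tree
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  d1 <- as.matrix(beta_distance(x, "weighted_unifrac", tree = tr))
  d2 <- as.matrix(beta_distance(x, "weighted_unifrac", tree = tr2))
  expect_equal(d1, d2, tolerance = 1e-12)
  # taxa absent from the tree are an error naming offenders
  xx <- rbind(x, extra = 1)
  expect_error(beta_distance(xx, "weighted_unifrac", tree = tr), "extra")
  expect_error(beta_distance(x, "weighted_unifrac"), "tree")
})

test_that("UniFrac agrees with the phyloseq reference implementation", {
  skip_if_not_installed("phyloseq")
  co <- generate_cohort(small_config(seed = 35L, n_per_group = 4L,
                                     n_taxa = 8L))
  x <- unclass(co$counts) + 0
  ps <- phyloseq::phyloseq(phyloseq::otu_table(x, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(co$tree))
  ref_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  ids <- colnames(x)
  got_u <- as.matrix(beta_distance(x, "unweighted_unifrac", tree = co$tree))
  got_w <- as.matrix(beta_distance(x, "weighted_unifrac", tree = co$tree))
  expect_equal(got_u[ids, ids], ref_u[ids, ids], tolerance = 1e-8)
  expect_equal(got_w[ids, ids], ref_w[ids, ids], tolerance = 1e-8)
})
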