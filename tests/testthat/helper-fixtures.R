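# Shared fixture builders and independent oracles.

toy_counts <- function(m = NULL, taxa = NULL, samples = NULL) {
  if (is.null(m))
    m <- matrix(c(5L, 0L, 3L,
                  1L, 2L, 8L), nrow = 2L, byrow = TRUE)
  rownames(m) <- taxa %||% sprintf("t%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  count_table(m)
}

write_counts_tsv <- function(m, path = tempfile(fileext = ".tsv"),
                             id_col = "taxon_id") {
  df <- data.frame(x = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_meta <- function(n = 6L, groups = rep(c("HC", "CD", "UC"), length.out = n)) {
  metadata_frame(
    data.frame(group = groups,
               age = seq(25, by = 5, length.out = n),
               cereals = rep(c("yes", "no"), length.out = n)),
    sample_ids = sprintf("s%d", seq_len(n)),
    target = "group")
}

# Independent per-branch UniFrac oracle: recursive descendant enumeration,
# direct evaluation of the branch-sum formulas.
oracle_unifrac <- function(tree, xa, xb, metric, alpha = 0.5) {
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, desc))
  }
  pa <- xa / sum(xa); pb <- xb / sum(xb)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc(tree$edge[e, 2L])]
    l <- tree$edge.length[e]
    qa <- sum(pa[tips]); qb <- sum(pb[tips])
    if (metric == "unweighted") {
      ia <- qa > 0; ib <- qb > 0
      if (ia || ib) { den <- den + l; if (xor(ia, ib)) num <- num + l }
    } else if (metric == "weighted") {
      num <- num + l * abs(qa - qb)
      den <- den + l * (qa + qb)
    } else {
      if (qa + qb > 0) {
        w <- l * (qa + qb)^alpha
        num <- num + w * abs(qa - qb) / (qa + qb)
        den <- den + w
      }
    }
  }
  if (den == 0) 0 else num / den
}

# One-way ANOVA pseudo-F oracle on a relabelling of a distance matrix,
# via explicit within/between sums of squares of the Gower matrix.
oracle_permanova_f <- function(d, groups) {
  n <- nrow(d)
  a <- -0.5 * d^2
  G <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  X <- model.matrix(~groups)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ss_model <- sum(H * G)
  ss_res <- sum(diag(G)) - ss_model
  df1 <- nlevels(factor(groups)) - 1L
  (ss_model / df1) / (ss_res / (n - df1 - 1L))
}

# Brute-force step-up BH oracle: min over k >= i of m * p_(k) / k.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# A small cohort config used across tests.
small_config <- function(seed = 1L, n_per_group = 20L, n_taxa = 12L, ...) {
  synthetic_config(groups = c(HC = n_per_group, CD = n_per_group,
                              UC = n_per_group),
                   n_taxa = n_taxa, seed = seed, ...)
}
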