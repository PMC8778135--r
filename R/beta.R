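#' Beta-diversity dissimilarity matrix
#'
#' Computes one of five between-sample dissimilarities on a (normalized)
#' abundance table:
#' \itemize{
#'   \item `bray_curtis`: `sum|x - y| / sum(x + y)`.
#'   \item `canberra`: `(1/NZ) sum |x - y| / (x + y)` over taxon pairs with
#'     `x + y > 0` (`NZ` = number of such pairs), bounded in `[0, 1]`.
#'   \item `unweighted_unifrac`: fraction of branch length unique to either
#'     sample (presence/absence).
#'   \item `weighted_unifrac`: abundance-weighted branch-length difference;
#'     normalized form (bounded `[0, 1]`) by default, raw form via
#'     `normalized = FALSE`.
#'   \item `generalized_unifrac`: exponent `alpha` interpolates between
#'     emphasis on rare (`alpha = 0`) and abundant (`alpha = 1`, identical
#'     to the normalized weighted form) lineages; default 0.5.
#' }
#'
#' @param x abundance matrix, taxa x samples (counts or normalized).
#' @param metric one of the five metric names above.
#' @param tree rooted `phylo` covering all taxa (UniFrac only).
#' @param alpha generalized-UniFrac exponent in `[0, 1]`.
#' @param normalized use the normalized weighted-UniFrac form.
#' @return a [distance_matrix()].
#' @export
beta_distance <- function(x, metric = c("bray_curtis", "canberra",
                                        "unweighted_unifrac",
                                        "weighted_unifrac",
                                        "generalized_unifrac"),
                          tree = NULL, alpha = 0.5, normalized = TRUE) {
  metric <- match.arg(metric)
  x <- unclass(x) + 0
  if (any(colSums(x) <= 0))
    abort_mc("beta diversity undefined for all-zero samples", "mc_validation_error")
  if (metric %in% c("bray_curtis", "canberra")) {
    method <- c(bray_curtis = "bray", canberra = "canberra")[[metric]]
    d <- vegan::vegdist(t(x), method = method)
    return(distance_matrix(as.matrix(d), metric = metric))
  }
  if (is.null(tree))
    abort_mc(sprintf("metric '%s' requires a phylogenetic tree", metric),
             "mc_validation_error")
  if (alpha < 0 || alpha > 1)
    abort_mc("generalized-UniFrac alpha must be in [0, 1]", "mc_config_error")
  d <- unifrac_matrix(x, tree, metric, alpha = alpha, normalized = normalized)
  distance_matrix(d, metric = metric)
}

# Per-edge tip incidence of a rooted tree: logical matrix (edges x tips).
edge_tip_incidence <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  inc <- matrix(FALSE, ntip + nnode, ntip)
  inc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    inc[par, ] <- inc[par, ] | inc[ch, ]
  }
  list(tree = tree,
       incidence = inc[tree$edge[, 2L], , drop = FALSE],
       lengths = tree$edge.length)
}

unifrac_matrix <- function(x, tree, metric, alpha = 0.5, normalized = TRUE) {
  taxa <- rownames(x)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L)
    abort_mc(paste0("taxa absent from tree: ", paste(missing, collapse = ", ")),
             "mc_validation_error")
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra) > 0L) tree <- ape::drop.tip(tree, extra)
  et <- edge_tip_incidence(tree)
  inc <- et$incidence[, match(taxa, et$tree$tip.label), drop = FALSE]
  len <- et$lengths
  p <- sweep(x, 2L, colSums(x), `/`)                 # tips x samples proportions
  pe <- (inc * 1) %*% p                              # edges x samples
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  present <- pe > 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- unifrac_pair(pe[, i], pe[, j], present[, i],
                                       present[, j], len, metric, alpha,
                                       normalized)
  }
  d
}

unifrac_pair <- function(pa, pb, ia, ib, len, metric, alpha, normalized) {
  if (metric == "unweighted_unifrac") {
    either <- ia | ib
    denom <- sum(len[either])
    if (denom == 0) return(0)
    return(sum(len[xor(ia, ib)]) / denom)
  }
  if (metric == "weighted_unifrac") {
    num <- sum(len * abs(pa - pb))
    if (!normalized) return(num)
    denom <- sum(len * (pa + pb))
    return(if (denom == 0) 0 else num / denom)
  }
  # generalized UniFrac
  tot <- pa + pb
  keep <- tot > 0
  w <- len[keep] * tot[keep]^alpha
  denom <- sum(w)
  if (denom == 0) return(0)
  sum(w * abs(pa[keep] - pb[keep]) / tot[keep]) / denom
}
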