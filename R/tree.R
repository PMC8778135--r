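#' Read a rooted phylogenetic tree from Newick
#'
#' UniFrac metrics require a rooted tree; unrooted input (basal
#' multifurcation) is midpoint-rooted. Missing branch lengths become 0.
#' Tips may be a superset of the count-table taxa; pruning happens lazily
#' when a UniFrac distance is computed.
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object, rooted.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    abort_mc(paste0("unparseable Newick file: ", conditionMessage(e)),
             "mc_parse_error"))
  if (is.null(tree))
    abort_mc("unparseable Newick file", "mc_parse_error")
  if (anyDuplicated(tree$tip.label))
    abort_mc("duplicated tip labels in tree", "mc_validation_error")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (!ape::is.rooted(tree)) {
    message("input tree is unrooted; midpoint-rooting it")
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' Construct a validated sample-by-sample distance matrix
#'
#' @param d symmetric non-negative matrix with zero diagonal and sample
#'   identifiers as dimnames, or a [stats::dist].
#' @param metric name of the dissimilarity metric.
#' @return a `distance_matrix`: classed symmetric matrix with attribute
#'   `metric`.
#' @export
distance_matrix <- function(d, metric = "unknown") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.null(rownames(d))) abort_mc("distance matrix needs sample names",
                                     "mc_validation_error")
  if (!isSymmetric(unname(d), tol = 1e-8))
    abort_mc("distance matrix must be symmetric", "mc_validation_error")
  if (any(!is.finite(d)) || any(d < -1e-12))
    abort_mc("distances must be finite and non-negative", "mc_validation_error")
  if (any(abs(diag(d)) > 1e-12))
    abort_mc("distance matrix must have a zero diagonal", "mc_validation_error")
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  structure(d, metric = metric, class = c("distance_matrix", class(d)))
}
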