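# Phylogenetic mapping of structural data: root distances, depth
# correlations, clustering against clades.

#' Root-to-node path lengths
#'
#' Sum of branch lengths from the root to every node (the node's own
#' branch included); the root maps to 0.
#'
#' @param tree rooted `phylo` with node labels and branch lengths
#' @return named numeric vector, node id -> distance (substitutions/site)
#' @export
root_distances <- function(tree) {
  validate_phylo(tree)
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d, node_ids(tree))
}

#' Spearman rank correlation with optional permutation p-value
#'
#' Rank correlation with average ranks for ties, computed as the Pearson
#' correlation of the rank vectors. The p-value, when requested, is a
#' two-sided seeded permutation test (no analytic approximation).
#'
#' @param x,y equal-length numeric vectors (n >= 3)
#' @param n_perm permutations for the p-value; 0 skips it
#' @param seed integer seed for the permutations
#' @return list: rho, n, p (NA when n_perm = 0)
#' @export
spearman <- function(x, y, n_perm = 0, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stopf("rank correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- NA_real_
  if (n_perm > 0) {
    rx <- rank(x); ry <- rank(y)
    obs <- abs(rho)
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i)
        abs(stats::cor(rx, sample(ry))) >= obs - 1e-12, logical(1)))
    })
    p <- (hits + 1) / (n_perm + 1)
  }
  list(rho = rho, n = n, p = p)
}

#' Correlation between a structural attribute and root distance
#'
#' Spearman correlation of the attribute against the phylogenetic distance
#' from the root, over the nodes present in both the tree and the
#' attribute table (others are silently excluded; `n` reports the overlap).
#'
#' @param tree rooted `phylo`
#' @param attr_table data.frame with a `structure_id` column (node ids)
#' @param attribute_name column to correlate
#' @param n_perm,seed permutation p-value settings (see [spearman()])
#' @return list: rho, n, p
#' @export
attribute_depth_correlation <- function(tree, attr_table, attribute_name,
                                        n_perm = 0, seed = 1) {
  if (!attribute_name %in% names(attr_table))
    stopf("attribute '%s' not in table", attribute_name)
  depth <- root_distances(tree)
  ids <- intersect(attr_table$structure_id, names(depth))
  vals <- attr_table[[attribute_name]][match(ids, attr_table$structure_id)]
  ok <- is.finite(vals)
  if (sum(ok) < 3) stopf("fewer than 3 nodes with both depth and attribute")
  spearman(depth[ids][ok], vals[ok], n_perm = n_perm, seed = seed)
}

#' Average-linkage hierarchical clustering of a distance matrix
#'
#' @param matrix symmetric pairwise-distance matrix with zero diagonal and
#'   id dimnames
#' @param k number of flat clusters to cut
#' @return `cluster_result`: list with `hclust` (merge record), `labels`
#'   (named integer cluster labels at k), `ids`, `k`
#' @export
hierarchical_cluster <- function(matrix, k) {
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-8)))
    stopf("distance matrix must be symmetric")
  if (any(abs(diag(matrix)) > 1e-8)) stopf("diagonal must be zero")
  if (anyNA(matrix)) stopf("distance matrix contains missing pairs")
  n <- nrow(matrix)
  if (k > n) stopf("k = %d exceeds number of items (%d)", k, n)
  hc <- stats::hclust(stats::as.dist(matrix), method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, labels = labels,
                 ids = rownames(matrix), k = k),
            class = "cluster_result")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same ids,
#' computed from the contingency table.
#'
#' @param labels_clusters,labels_clades named vectors labelling the same
#'   ids (names are matched; unnamed vectors are matched by position)
#' @return ARI in [-1, 1]
#' @export
clade_recovery <- function(labels_clusters, labels_clades) {
  if (!is.null(names(labels_clusters)) && !is.null(names(labels_clades))) {
    if (!setequal(names(labels_clusters), names(labels_clades)))
      stopf("labelings cover different ids")
    labels_clades <- labels_clades[names(labels_clusters)]
  } else if (length(labels_clusters) != length(labels_clades)) {
    stopf("labelings differ in length")
  }
  tab <- table(labels_clusters, labels_clades)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-12) return(0)  # degenerate partitions
  (sum_ij - expected) / (maxi - expected)
}
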