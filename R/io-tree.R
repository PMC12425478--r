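# Rooted-phylogeny IO and node-id bookkeeping on top of ape.
#
# Trees are plain ape "phylo" objects. Every node (tip and internal) must
# carry a unique label; internal labels name ancestral nodes and link them
# to posterior tables and predicted structures. Clade labels, when present,
# live in a named character vector attribute "clade_labels" (node id ->
# clade name; nodes on the backbone above all clades may be absent).

#' Read a rooted newick tree with internal node labels
#'
#' @param path newick file path
#' @return an ape `phylo` object, validated (rooted, unique labels,
#'   non-negative branch lengths)
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("newick file not found: %s", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stopf("could not parse newick in '%s'", path)
  validate_phylo(tr)
}

#' Write a tree (with any clade labels dropped) to newick
#' @param tree `phylo` object
#' @param path output path
#' @return invisibly, `path`
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate the phylogeny contract used throughout the package
#' @param tree `phylo` object
#' @return `tree`, invisibly-compatible (returned for chaining)
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylo object")
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  if (is.null(tree$edge.length)) stopf("tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  if (is.null(tree$node.label) || any(is.na(tree$node.label)) ||
      any(tree$node.label == ""))
    stopf("all internal nodes must be labelled (ancestor ids)")
  ids <- node_ids(tree)
  if (anyDuplicated(ids))
    stopf("duplicate node ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tree
}

#' All node ids (tips then internal nodes) in ape node-number order
#' @param tree `phylo` object
#' @return character vector, element k is the id of ape node number k
#' @export
node_ids <- function(tree) c(tree$tip.label, tree$node.label)

# id -> ape node number
node_number <- function(tree, id) {
  n <- match(id, node_ids(tree))
  if (anyNA(n)) stopf("unknown node id(s): %s",
                      paste(id[is.na(n)], collapse = ", "))
  n
}

# children (ape numbers) of a node
node_children <- function(tree, num)
  tree$edge[tree$edge[, 1] == num, 2]

# tip ids descending from a node id (the node itself if a tip)
descendant_tips <- function(tree, id) {
  num <- node_number(tree, id)
  ntip <- length(tree$tip.label)
  if (num <= ntip) return(tree$tip.label[num])
  out <- integer(0)
  stack <- num
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- node_children(tree, v)
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tree$tip.label[sort(out)]
}

#' Clade labels attached to a tree
#' @param tree `phylo` object
#' @return named character vector (node id -> clade label), or NULL
#' @export
clade_labels <- function(tree) attr(tree, "clade_labels")

#' Attach clade labels to a tree
#' @param tree `phylo` object
#' @param labels named character vector, node id -> clade label
#' @return the tree with the labels attached
#' @export
set_clade_labels <- function(tree, labels) {
  unknown <- setdiff(names(labels), node_ids(tree))
  if (length(unknown))
    stopf("clade labels name unknown nodes: %s",
          paste(unknown, collapse = ", "))
  attr(tree, "clade_labels") <- labels
  tree
}
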