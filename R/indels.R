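# Insertion/deletion events: block detection on the alignment, Fitch
# parsimony branch assignment, and per-lineage length trajectories.
#
# Alignment-column intervals are 0-based and half-open throughout:
# a block [start, end) spans columns start+1 .. end in 1-based R indexing.

presence_in_block <- function(mat, start, end) {
  cols <- (start + 1):end
  rowSums(mat[, cols, drop = FALSE] != "-") > 0
}

#' Detect candidate insertion/deletion blocks in an alignment
#'
#' Columns containing at least one gap are merged left-to-right into
#' blocks while consecutive columns have similar presence sets: Jaccard
#' similarity at least `merge_jaccard`, or one set nested within the other
#' (which keeps a progressively elongating terminal extension as a single
#' block). Blocks shorter than `min_block` columns are discarded.
#'
#' @param msa named character vector of gapped sequences (typically the
#'   leaf rows; pass internal rows too if block presence should reflect
#'   ancestors)
#' @param min_block minimum block width in columns (default 5)
#' @param merge_jaccard presence-set Jaccard threshold for merging
#'   adjacent columns (default 0.9)
#' @return list of blocks: each a list with `start`, `end` (0-based,
#'   half-open), `span`, `presence` (row names carrying the block)
#' @export
detect_indel_blocks <- function(msa, min_block = 5, merge_jaccard = 0.9) {
  mat <- msa_matrix(msa)
  ncol_aln <- ncol(mat)
  gapped <- colSums(mat == "-") > 0
  if (!any(gapped)) return(list())
  colsets <- lapply(seq_len(ncol_aln), function(j)
    rownames(mat)[mat[, j] != "-"])
  jacc <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 1 else length(intersect(a, b)) / u
  }
  nested <- function(a, b) all(a %in% b) || all(b %in% a)
  blocks <- list()
  j <- 1L
  while (j <= ncol_aln) {
    if (!gapped[j]) { j <- j + 1L; next }
    start <- j
    while (j < ncol_aln && gapped[j + 1L] &&
           (jacc(colsets[[j]], colsets[[j + 1L]]) >= merge_jaccard ||
            nested(colsets[[j]], colsets[[j + 1L]])))
      j <- j + 1L
    end <- j
    if (end - start + 1L >= min_block) {
      pres <- rownames(mat)[presence_in_block(mat, start - 1L, end)]
      blocks[[length(blocks) + 1L]] <-
        list(start = start - 1L, end = end, span = end - start + 1L,
             presence = pres)
    }
    j <- j + 1L
  }
  blocks
}

#' Fitch parsimony reconstruction of a binary presence character
#'
#' Bottom-up set Fitch followed by a top-down pass resolving ambiguity by
#' preferring absence (state 0) at the root, so clade-restricted blocks
#' are explained as insertions rather than deletions whenever the change
#' count allows it.
#'
#' @param tree rooted `phylo` with node labels
#' @param leaf_states named logical/0-1 vector over all tips
#' @return list: `states` (named 0/1 over all nodes), `n_changes`
#' @export
fitch_presence <- function(tree, leaf_states) {
  validate_phylo(tree)
  miss <- setdiff(tree$tip.label, names(leaf_states))
  if (length(miss)) stopf("missing leaf states: %s",
                          paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip))
    sets[[i]] <- as.integer(leaf_states[[tree$tip.label[i]]] != 0)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(po))) {       # child sets are ready before parents
    parent <- po[r, 1]; child <- po[r, 2]
    sets[[parent]] <- if (is.null(sets[[parent]])) sets[[child]]
      else if (length(intersect(sets[[parent]], sets[[child]])))
        intersect(sets[[parent]], sets[[child]])
      else union(sets[[parent]], sets[[child]])
  }
  root <- ntip + 1L
  states <- integer(nnode)
  states[root] <- if (0L %in% sets[[root]]) 0L else 1L
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]   # preorder edges
  for (r in seq_len(nrow(pre))) {
    parent <- pre[r, 1]; child <- pre[r, 2]
    states[child] <- if (states[parent] %in% sets[[child]]) states[parent]
      else sets[[child]][1]
  }
  n_changes <- sum(states[pre[, 1]] != states[pre[, 2]])
  list(states = stats::setNames(states, node_ids(tree)),
       n_changes = n_changes)
}

#' Assign indel blocks to tree branches
#'
#' For each block, the presence/absence state of every node is either read
#' directly from ancestral alignment rows (when the alignment contains
#' them) or reconstructed by Fitch parsimony from the leaves. Every edge
#' on which the state flips becomes an event: 0 to 1 is an insertion, 1 to
#' 0 a deletion, attributed to the child node of the branch.
#'
#' @param blocks output of [detect_indel_blocks()]
#' @param tree rooted `phylo` with node labels matching alignment rows
#' @param msa the alignment (leaf rows required; internal-node rows used
#'   as ancestral states when present)
#' @return list of events: each a list with `start`, `end`,
#'   `event_branch` (child node id), `direction` ("insertion" or
#'   "deletion"), and `length_by_node` (named residue counts inside the
#'   block for every node with an alignment row)
#' @export
assign_events_to_branches <- function(blocks, tree, msa) {
  validate_phylo(tree)
  mat <- msa_matrix(msa)
  ids <- node_ids(tree)
  ntip <- length(tree$tip.label)
  have_anc <- all(tree$node.label %in% rownames(mat))
  events <- list()
  for (b in blocks) {
    pres_rows <- intersect(b$presence, rownames(mat))
    leaf_states <- stats::setNames(tree$tip.label %in% pres_rows,
                                   tree$tip.label)
    if (!any(leaf_states))
      stopf("block [%d, %d) present in no leaf", b$start, b$end)
    if (have_anc) {
      states <- stats::setNames(integer(length(ids)), ids)
      states[rownames(mat)] <- as.integer(
        presence_in_block(mat, b$start, b$end))
    } else {
      states <- fitch_presence(tree, leaf_states)$states
    }
    lengths_by_node <- rowSums(
      mat[, (b$start + 1):b$end, drop = FALSE] != "-")
    edges <- tree$edge
    for (r in seq_len(nrow(edges))) {
      ps <- states[[ids[edges[r, 1]]]]
      cs <- states[[ids[edges[r, 2]]]]
      if (ps != cs)
        events[[length(events) + 1L]] <- list(
          start = b$start, end = b$end,
          event_branch = ids[edges[r, 2]],
          direction = if (cs > ps) "insertion" else "deletion",
          length_by_node = lengths_by_node)
    }
  }
  events
}

#' Insertion length along a root-to-tip lineage
#'
#' Residue count inside the event's block columns for every node on the
#' path from the root to `lineage_tip`, in root-to-tip order. Nodes
#' without an alignment row are reported as NA (missing).
#'
#' @param event an event from [assign_events_to_branches()] (or any list
#'   with `start` and `end`)
#' @param tree rooted `phylo`
#' @param msa alignment including ancestral rows for the path interior
#' @param lineage_tip leaf id ending the lineage
#' @return data.frame: node, length (block-column residue count)
#' @export
length_trajectory <- function(event, tree, msa, lineage_tip) {
  validate_phylo(tree)
  mat <- msa_matrix(msa)
  ids <- node_ids(tree)
  tip_num <- node_number(tree, lineage_tip)
  if (tip_num > length(tree$tip.label)) stopf("'%s' is not a leaf",
                                              lineage_tip)
  path <- ape::nodepath(tree, from = length(tree$tip.label) + 1L,
                        to = tip_num)
  counts <- vapply(ids[path], function(id) {
    if (!id %in% rownames(mat)) return(NA_integer_)
    sum(mat[id, (event$start + 1):event$end] != "-")
  }, integer(1))
  if (any(counts > event$end - event$start, na.rm = TRUE))
    stopf("internal error: count exceeds block span")
  data.frame(node = ids[path], length = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
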