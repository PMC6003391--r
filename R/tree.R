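#' Read and write rooted trees in Newick format
#'
#' Thin wrappers around the `ape` Newick parser that enforce the
#' requirements of the purity analyses: the tree is used as rooted in the
#' file (no re-rooting), multifurcations are preserved, leaf labels must be
#' unique, and obvious syntax errors (unbalanced parentheses) are reported
#' with their character position. Internal node labels and branch lengths
#' are retained but ignored by all purity computations.
#'
#' @param text A Newick string, or `NULL` to read from `file`.
#' @param file Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply text or file")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[[i]] == "(") depth <- depth + 1L
    if (chars[[i]] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at position ", i)
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unclosed at end of input")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick input")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) writeLines(s, file)
  invisible(s)
}

# Tip indices under every node (tips included as themselves), computed by one
# postorder accumulation over the edge matrix; degree-agnostic.
tips_under <- function(tree) {
  n <- Ntip(tree)
  res <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) res[[i]] <- i
  eo <- stats::reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    res[[eo[k, 1L]]] <- c(res[[eo[k, 1L]]], res[[eo[k, 2L]]])
  }
  res
}

# Parent of every node (0 for the root).
node_parents <- function(tree) {
  par <- integer(Ntip(tree) + tree$Nnode)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

#' Lowest common ancestor of a set of leaves
#'
#' Returns the lowest node whose subtree contains all the named leaves.
#' A single leaf is its own LCA (returned as the tip's node number).
#'
#' @param tree A rooted `phylo` object.
#' @param leaf_ids Character vector of leaf labels (non-empty).
#' @return A node number (tips are `1..Ntip`, internals follow).
#' @export
lca <- function(tree, leaf_ids) {
  leaf_ids <- unique(as.character(leaf_ids))
  if (!length(leaf_ids)) stop("leaf_ids must be non-empty")
  tip <- match(leaf_ids, tree$tip.label)
  if (anyNA(tip)) {
    stop("unknown leaf id(s): ", paste(leaf_ids[is.na(tip)], collapse = ", "))
  }
  if (length(tip) == 1L) return(tip)
  getMRCA(tree, tip)
}

#' Extract the induced subset tree for a set of leaves
#'
#' Prunes all leaves outside `keep`, suppresses the resulting unary
#' internal nodes (summing branch lengths along suppressed paths) and
#' returns the induced rooted topology, rooted at the LCA of `keep`. This
#' is how a guide tree is restricted to the common subset of sequences
#' shared with other databases before comparing branching orders.
#'
#' @param tree A rooted `phylo` object.
#' @param keep Character vector of leaf labels, at least 2.
#' @return A `phylo` object with `length(keep)` leaves.
#' @export
extract_subset_tree <- function(tree, keep) {
  keep <- unique(as.character(keep))
  if (length(keep) < 2L) stop("need at least 2 leaves to extract a subset tree")
  miss <- setdiff(keep, tree$tip.label)
  if (length(miss)) stop("leaves not in tree: ", paste(miss, collapse = ", "))
  keep.tip(tree, keep)
}
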