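# Rooted-tree utilities layered over ape's "phylo" representation.
#
# All functions use ape's node numbering: tips are 1..Ntip, the root is
# Ntip+1, and internal nodes follow. Polytomies are allowed throughout;
# several consumers (reconciliation, Dollo) rely on that.

#' Read a rooted tree from a newick file or string
#'
#' Thin wrapper around [ape::read.tree()] that insists on a rooted tree:
#' downstream reconciliation and parsimony reconstructions are only defined
#' on rooted trees, and silent midpoint/outgroup rooting would hide an input
#' error.
#'
#' @param x Path to a newick file, or a newick string (must contain "(").
#' @return An object of class `phylo`, guaranteed rooted.
#' @export
read_rooted_tree <- function(x) {
  phy <- if (length(x) == 1 && grepl("\\(", x) && !file.exists(x)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(x)
  }
  if (is.null(phy)) stop("could not parse newick input")
  assert_rooted(phy)
  phy
}

#' @keywords internal
assert_rooted <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' tree")
  if (!ape::is.rooted(phy)) {
    stop("tree is unrooted; reconciliation and ancestral-state inference ",
         "require explicitly rooted input (no silent rooting is applied)")
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicated tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  invisible(phy)
}

# parent node of every node (0 for the root)
#' @keywords internal
tree_parents <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- integer(n)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

# children of every node, as a list indexed by node id
#' @keywords internal
tree_children <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    ch[[phy$edge[i, 1]]] <- c(ch[[phy$edge[i, 1]]], phy$edge[i, 2])
  }
  ch
}

# depth in edges from the root (root = 0)
#' @keywords internal
node_depths <- function(phy) {
  par <- tree_parents(phy)
  root <- root_node(phy)
  n <- length(par)
  dep <- rep(NA_integer_, n)
  dep[root] <- 0L
  # nodes in phy$edge are listed parent-before-child after reorder
  ord <- reorder_edges_preorder(phy)
  for (i in ord) {
    dep[phy$edge[i, 2]] <- dep[phy$edge[i, 1]] + 1L
  }
  dep
}

#' @keywords internal
root_node <- function(phy) ape::Ntip(phy) + 1L

# edge indices in preorder (every parent appears before its children)
#' @keywords internal
reorder_edges_preorder <- function(phy) {
  seen <- logical(ape::Ntip(phy) + phy$Nnode)
  seen[root_node(phy)] <- TRUE
  idx <- seq_len(nrow(phy$edge))
  out <- integer(0)
  remaining <- idx
  while (length(remaining)) {
    ready <- remaining[seen[phy$edge[remaining, 1]]]
    if (!length(ready)) stop("tree edges do not form a rooted tree")
    out <- c(out, ready)
    seen[phy$edge[ready, 2]] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  out
}

# postorder node sequence (children before parents, root last), tips included
#' @keywords internal
node_postorder <- function(phy) {
  pre <- c(root_node(phy), phy$edge[reorder_edges_preorder(phy), 2])
  rev(pre)
}

# ancestors of a node from itself up to the root (inclusive of both)
#' @keywords internal
ancestor_path <- function(par, node) {
  path <- node
  while (par[node] != 0L) {
    node <- par[node]
    path <- c(path, node)
  }
  path
}

# LCA of a set of node ids
#' @keywords internal
tree_lca <- function(phy, nodes, par = tree_parents(phy),
                     dep = node_depths(phy)) {
  nodes <- unique(nodes)
  if (!length(nodes)) stop("empty node set has no LCA")
  cur <- nodes[1]
  for (v in nodes[-1]) {
    a <- cur; b <- v
    while (dep[a] > dep[b]) a <- par[a]
    while (dep[b] > dep[a]) b <- par[b]
    while (a != b) { a <- par[a]; b <- par[b] }
    cur <- a
  }
  cur
}

# tip ids (integer) under each node, as a list indexed by node id
#' @keywords internal
tips_below <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  below <- vector("list", n)
  ch <- tree_children(phy)
  for (t in seq_len(ape::Ntip(phy))) below[[t]] <- t
  for (v in node_postorder(phy)) {
    if (v > ape::Ntip(phy)) below[[v]] <- unlist(below[ch[[v]]])
  }
  below
}

#' Stable human-readable labels for every node of a tree
#'
#' Tips keep their tip labels; internal nodes use `node.label` when present
#' and non-empty, otherwise `"node<k>"`. Branches are addressed everywhere in
#' this package by the label of their child node, which stays well defined in
#' the presence of polytomies.
#'
#' @param phy A `phylo` tree.
#' @return Character vector indexed by node id.
#' @export
node_labels <- function(phy) {
  ntip <- ape::Ntip(phy)
  lab <- character(ntip + phy$Nnode)
  lab[seq_len(ntip)] <- phy$tip.label
  internal <- ntip + seq_len(phy$Nnode)
  nl <- phy$node.label
  for (i in seq_along(internal)) {
    v <- internal[i]
    lab[v] <- if (!is.null(nl) && !is.na(nl[i]) && nzchar(nl[i])) nl[i]
              else paste0("node", v)
  }
  lab
}
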