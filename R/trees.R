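# Shared helpers on ape "phylo" trees.  Species trees are rooted binary
# phylo objects with unique tip labels and optional internal-node names
# (e.g. "amniote_ancestor"); gene trees are phylo objects whose tips are
# gene ids.

#' Validate a rooted binary tree
#' @param tree a `phylo`.
#' @param what label used in error messages.
#' @keywords internal
check_rooted_binary <- function(tree, what = "tree") {
  if (!inherits(tree, "phylo")) stop_invalid(what, " is not a phylo object")
  if (!ape::is.rooted(tree)) stop_invalid(what, " must be rooted")
  if (!ape::is.binary(tree)) stop_invalid(what, " must be binary")
  if (anyDuplicated(tree$tip.label))
    stop_invalid(what, " has duplicate tip labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop_invalid(what, " has negative branch lengths")
  invisible(tree)
}

# parent of every node (0 for the root)
node_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# children list per node
node_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]
    ch[[a]] <- c(ch[[a]], tree$edge[i, 2])
  }
  ch
}

# number of edges from the root to each node
node_depths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  d <- integer(n)
  eg <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # process edges parent-before-child
  po <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(po))) d[po[i, 2]] <- d[po[i, 1]] + 1L
  d
}

# time of each node measured from the root (sum of branch lengths)
node_times <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  t <- numeric(n)
  po <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(po$edge)))
    t[po$edge[i, 2]] <- t[po$edge[i, 1]] + po$edge.length[i]
  t
}

# age of each node: max path length down to a descendant tip
node_ages <- function(tree) {
  tt <- node_times(tree)
  n <- ape::Ntip(tree) + tree$Nnode
  age <- numeric(n)
  po <- ape::reorder.phylo(tree, "postorder")
  age[seq_len(ape::Ntip(tree))] <- 0
  for (i in seq_len(nrow(po$edge))) {
    a <- po$edge[i, 1]; b <- po$edge[i, 2]
    age[a] <- max(age[a], age[b] + po$edge.length[i])
  }
  age
}

# tip labels below each node
descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  sets <- vector("list", n)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    a <- po$edge[i, 1]; b <- po$edge[i, 2]
    sets[[a]] <- c(sets[[a]], sets[[b]])
  }
  lapply(sets, sort)
}

# human-readable name for a species-tree node: tip label, node label, or
# a generated signature over the descendant tip set
species_node_name <- function(tree, node, tipsets = NULL) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- tree$node.label[node - ntip]
  if (!is.null(lab) && !is.na(lab) && nzchar(lab)) return(lab)
  if (is.null(tipsets)) tipsets <- descendant_tips(tree)
  paste0("anc(", paste(tipsets[[node]], collapse = "+"), ")")
}

# lowest common ancestor of two nodes, from a parent vector
lca_nodes <- function(parents, a, b) {
  anc <- a
  x <- a
  while (parents[x] != 0L) { x <- parents[x]; anc <- c(anc, x) }
  y <- b
  while (!(y %in% anc)) y <- parents[y]
  y
}
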