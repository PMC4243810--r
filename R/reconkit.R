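# Gene-tree / species-tree reconciliation: LCA mapping, duplication
# calling with ancestral-branch age labels, embedding-based loss
# counting with a per-branch decomposition, and deterministic paralog
# naming (letters for ancient duplication clades, numeric suffixes for
# lineage-specific ones, trailing letters for within-species copies).

#' LCA reconciliation of a gene tree with a species tree
#'
#' Each gene-tree node is mapped to the species-tree LCA of its
#' descendants' species in one postorder pass.  A node is a duplication
#' iff it maps to the same species node as one of its children.  Losses
#' are counted along each gene-tree edge as the number of species-tree
#' edges skipped, with the usual adjustment below duplication nodes, and
#' attributed to the species-tree branches on which the lineage failed
#' to survive.  Duplications in clades with no extant descendants are
#' invisible to reconciliation by construction.
#'
#' @param gene_tree rooted binary `phylo`; tips are gene ids.
#' @param species_tree rooted binary `phylo`; tips are species.
#' @param leaf_map named character vector: gene id -> species.
#' @return A list of class `reconciliation`: `map` (gene node ->
#'   species node), `dup_nodes`, `losses_total`, `losses_by_branch`
#'   (named by the species node at the bottom of each branch),
#'   `copy_number`, plus the inputs.
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_map) {
  check_rooted_binary(gene_tree, "gene tree")
  check_rooted_binary(species_tree, "species tree")
  gtips <- gene_tree$tip.label
  unmapped <- setdiff(gtips, names(leaf_map))
  if (length(unmapped))
    stop_invalid("gene leaves missing from leaf map: ",
                 paste(unmapped, collapse = ", "))
  sp <- leaf_map[gtips]
  bad <- setdiff(unique(sp), species_tree$tip.label)
  if (length(bad))
    stop_invalid("species absent from species tree: ",
                 paste(bad, collapse = ", "))

  ngt <- ape::Ntip(gene_tree)
  nst <- ape::Ntip(species_tree)
  spar <- node_parents(species_tree)
  sdepth <- node_depths(species_tree)
  skids <- node_children(species_tree)
  stipsets <- descendant_tips(species_tree)

  M <- integer(ngt + gene_tree$Nnode)
  M[seq_len(ngt)] <- match(sp, species_tree$tip.label)
  po <- ape::reorder.phylo(gene_tree, "postorder")
  gkids <- node_children(gene_tree)
  for (i in seq(1, nrow(po$edge), by = 2)) {
    a <- po$edge[i, 1]
    ch <- gkids[[a]]
    M[a] <- lca_nodes(spar, M[ch[1]], M[ch[2]])
  }
  internal <- ngt + seq_len(gene_tree$Nnode)
  is_dup <- vapply(internal, function(v)
    any(M[gkids[[v]]] == M[v]), logical(1))
  dup_nodes <- internal[is_dup]

  # losses along each gene-tree edge, attributed per species branch
  branch_names <- vapply(seq_len(nst + species_tree$Nnode),
                         function(v) species_node_name(species_tree, v,
                                                       stipsets), "")
  losses <- setNames(numeric(nst + species_tree$Nnode), branch_names)
  gpar <- node_parents(gene_tree)
  for (v in seq_along(M)) {
    u <- gpar[v]
    if (u == 0L) next
    # species path M(u) = s0, ..., sk = M(v)
    path <- M[v]
    x <- M[v]
    while (x != M[u]) { x <- spar[x]; path <- c(path, x) }
    path <- rev(path)             # s0 ... sk
    k <- length(path) - 1L
    start <- if (u %in% dup_nodes) 1L else 2L
    # a loss at s_i means the lineage died out in the off-path child
    if (k >= 1 && start <= k) {
      for (ii in start:k) {
        s_above <- path[ii]       # s_{i-1}
        s_on <- path[ii + 1L]     # s_i
        off <- setdiff(skids[[s_above]], s_on)
        losses[off] <- losses[off] + 1
      }
    }
  }
  copy_number <- vapply(species_tree$tip.label,
                        function(s) sum(sp == s), integer(1))
  structure(list(map = M, dup_nodes = dup_nodes,
                 losses_total = sum(losses),
                 losses_by_branch = losses[losses > 0],
                 losses_all_branches = losses,
                 copy_number = copy_number,
                 gene_tree = gene_tree, species_tree = species_tree,
                 leaf_map = leaf_map),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("reconciliation: %d duplications, %g losses, %d species\n",
              length(x$dup_nodes), x$losses_total, length(x$copy_number)))
  invisible(x)
}

#' Label duplications with the age of their ancestral lineage
#'
#' Each duplication inherits the name of the species-tree node it maps
#' to: a supplied name, the species tree's own node label, or a
#' generated `anc(<tips>)` signature.  Duplications mapping to the same
#' species node that are nested in the gene tree are reported as an
#' ordered series via `series_rank` (1 = closest to the gene-tree root),
#' since their relative order within that ancestor is all the gene tree
#' can assert.
#'
#' @param rec a `reconciliation`.
#' @param named_ancestors optional named character vector mapping
#'   species-tree node numbers (as names) or node labels to display
#'   names.
#' @return data.frame with `node`, `species_node`, `label`,
#'   `series_rank`, `n_in_series`.
#' @export
label_duplication_ages <- function(rec, named_ancestors = NULL) {
  st <- rec$species_tree
  stipsets <- descendant_tips(st)
  gdepth <- node_depths(rec$gene_tree)
  labs <- vapply(rec$dup_nodes, function(v) {
    s <- rec$map[v]
    nm <- species_node_name(st, s, stipsets)
    if (!is.null(named_ancestors)) {
      if (as.character(s) %in% names(named_ancestors))
        nm <- named_ancestors[[as.character(s)]]
      else if (nm %in% names(named_ancestors))
        nm <- named_ancestors[[nm]]
    }
    nm
  }, "")
  df <- data.frame(node = rec$dup_nodes,
                   species_node = rec$map[rec$dup_nodes],
                   label = labs, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df$series_rank <- integer(0)
    df$n_in_series <- integer(0)
    return(df)
  }
  df$series_rank <- 1L
  df$n_in_series <- 1L
  for (s in unique(df$species_node)) {
    rows <- which(df$species_node == s)
    if (length(rows) > 1) {
      ord <- order(gdepth[df$node[rows]], df$node[rows])
      df$series_rank[rows[ord]] <- seq_along(rows)
      df$n_in_series[rows] <- length(rows)
    }
  }
  df[order(df$node), , drop = FALSE]
}

#' Losses decomposed by species-tree branch
#'
#' @param rec a `reconciliation`.
#' @return data.frame with `branch` (named by the species node at its
#'   bottom) and `losses`; the column sums to `rec$losses_total`.
#' @export
count_losses_per_lineage <- function(rec) {
  l <- rec$losses_all_branches
  data.frame(branch = names(l), losses = unname(l),
             stringsAsFactors = FALSE)
}

#' Assign paralog-group names
#'
#' Gene names are built from a family prefix plus tiered components:
#' clades descending from duplications whose mapped species node is at
#' least `letter_min_age` old receive capital letters (A, B, C ... by
#' decreasing clade size, ties broken by the lexicographically earliest
#' leaf id); younger duplications mapping to internal species nodes
#' yield numeric suffixes (same ordering); within-species duplicates
#' receive trailing lower-case letters when a number is already present
#' on their path, and numbers otherwise.  Letters and numbers do not by
#' themselves assert orthology across clades.
#'
#' @param rec a `reconciliation`.
#' @param family_prefix name prefix (e.g. `"Lyg"`).
#' @param lineage_rules list; `letter_min_age` (in species-tree time
#'   units) separates the letter tier from the numeric tier.  Default:
#'   half the species-tree height.
#' @return data.frame with `gene`, `species`, `name`.
#' @export
assign_names <- function(rec, family_prefix = "Lyg",
                         lineage_rules = list()) {
  gt <- rec$gene_tree
  st <- rec$species_tree
  ntip <- ape::Ntip(gt)
  ages <- node_ages(st)
  letter_min_age <- lineage_rules$letter_min_age %||%
    (max(node_ages(st)) / 2)
  gpar <- node_parents(gt)
  gtipsets <- descendant_tips(gt)

  tier <- setNames(rep("", length(rec$dup_nodes)),
                   as.character(rec$dup_nodes))
  for (v in rec$dup_nodes) {
    s <- rec$map[v]
    tier[[as.character(v)]] <-
      if (ages[s] >= letter_min_age) "letter"
      else if (s > ape::Ntip(st)) "number"
      else "species"
  }
  dup_tier <- function(v) {
    t <- tier[as.character(v)]
    if (is.na(t)) "" else t
  }

  # per leaf: the innermost node on its root path whose parent is a
  # duplication of the given tier ("unit" membership); ages are
  # non-increasing down the gene tree, so letter units always enclose
  # number units
  unit_of <- function(leaf, t) {
    unit <- NA_integer_
    v <- leaf
    path <- v
    while (gpar[v] != 0L) { v <- gpar[v]; path <- c(path, v) }
    path <- rev(path)               # root ... leaf
    for (i in seq_along(path)[-1]) {
      if (dup_tier(path[i - 1]) == t) unit <- path[i]
    }
    unit
  }
  leaves <- seq_len(ntip)
  lunit <- vapply(leaves, unit_of, integer(1), t = "letter")
  nunit <- vapply(leaves, unit_of, integer(1), t = "number")

  # rank units by decreasing exclusive leaf count, ties by the
  # lexicographically earliest member leaf
  rank_units <- function(membership, subset = rep(TRUE, ntip)) {
    ids <- sort(unique(membership[subset & !is.na(membership)]))
    if (!length(ids)) return(integer(0))
    sizes <- vapply(ids, function(u)
      sum(subset & !is.na(membership) & membership == u), integer(1))
    firsts <- vapply(ids, function(u)
      min(gt$tip.label[subset & !is.na(membership) & membership == u]), "")
    setNames(order(order(-sizes, firsts)), ids)   # unit id -> rank
  }

  lrank <- rank_units(lunit)
  comp_letter <- rep("", ntip)
  if (length(lrank))
    comp_letter[!is.na(lunit)] <-
      LETTERS[lrank[as.character(lunit[!is.na(lunit)])]]

  # number units are ranked within each letter group (shared letter
  # unit, or the residual no-letter group)
  comp_number <- rep("", ntip)
  lgroup <- ifelse(is.na(lunit), 0L, lunit)
  for (g in unique(lgroup)) {
    subset <- lgroup == g
    nrank <- rank_units(nunit, subset)
    sel <- subset & !is.na(nunit)
    if (length(nrank))
      comp_number[sel] <- as.character(nrank[as.character(nunit[sel])])
  }

  # within-species duplicates: letter suffixes when a number component
  # is already present on the path, numeric suffixes otherwise
  comp_suffix <- rep("", ntip)
  key <- paste(rec$leaf_map[gt$tip.label], comp_letter, comp_number,
               ifelse(is.na(nunit), 0L, nunit), sep = "\r")
  for (kk in unique(key)) {
    idx <- which(key == kk)
    if (length(idx) > 1) {
      idx <- idx[order(gt$tip.label[idx])]
      comp_suffix[idx] <- if (nzchar(comp_number[idx[1]]))
        letters[seq_along(idx)] else as.character(seq_along(idx))
    }
  }

  data.frame(gene = gt$tip.label,
             species = unname(rec$leaf_map[gt$tip.label]),
             name = paste0(family_prefix, comp_letter, comp_number,
                           comp_suffix),
             stringsAsFactors = FALSE)
}

#' Collapse weakly supported internal edges
#'
#' Robustness helper: internal edges of an unrooted gene tree with
#' bootstrap support below `threshold` are collapsed into
#' multifurcations (via [ape::di2multi] semantics on support values).
#' Reconciliation of a multifurcation is not attempted here; collapse is
#' for inspection and for duplication-minimizing resolutions upstream.
#'
#' @param tree `phylo` whose `node.label` holds numeric supports.
#' @param threshold minimal support to keep an edge (percent).
#' @return A `phylo`, possibly multifurcating.
#' @export
collapse_weak_edges <- function(tree, threshold = 50) {
  sup <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- ape::Ntip(tree)
  drop <- which(!is.na(sup) & sup < threshold) + ntip
  drop <- setdiff(drop, ntip + 1L)  # never collapse the root
  if (!length(drop)) return(tree)
  keep <- !(tree$edge[, 2] %in% drop)
  tree$edge.length[!keep] <- 0
  ape::di2multi(tree, tol = 1e-12)
}
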