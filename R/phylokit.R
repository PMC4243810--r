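# Distance-based phylogeny: pairwise-deletion p-distances with analytic
# multiple-hit corrections, Saitou-Nei neighbor joining, column-resampled
# bootstrap support, and outgroup rooting.

#' Proportion of differing sites between two alignment rows
#'
#' Pairwise deletion: only columns where both rows carry a residue are
#' counted.
#'
#' @param aln an `aligned_set`.
#' @param pair two row ids (character) or indices.
#' @param min_overlap sites required before a distance is defined
#'   (default 20).
#' @return A list with `p`, `n_sites`, and `undefined` (TRUE when the
#'   usable overlap is below `min_overlap`).
#' @export
p_distance <- function(aln, pair, min_overlap = 20) {
  m <- as.matrix(aln)
  if (is.character(pair)) pair <- match(pair, aln$ids)
  if (anyNA(pair)) stop_invalid("row not present in the alignment")
  a <- m[pair[1], ]; b <- m[pair[2], ]
  use <- a != "-" & b != "-"
  n <- sum(use)
  if (n < min_overlap)
    return(list(p = NA_real_, n_sites = n, undefined = TRUE))
  list(p = sum(a[use] != b[use]) / n, n_sites = n, undefined = FALSE)
}

#' Poisson-corrected protein distance
#'
#' `d = -ln(1 - p)`; saturated inputs (`p >= 1`) are undefined (`NA`).
#'
#' @param p proportion of differing sites, in `[0, 1)`.
#' @return Corrected distance (vectorized).
#' @export
poisson_distance <- function(p) {
  d <- ifelse(!is.na(p) & p < 1, -log(1 - p), NA_real_)
  d
}

# 20-state uniform-exchange correction (used for simulator calibration)
k20_distance <- function(p) {
  ifelse(!is.na(p) & p < 19 / 20, -(19 / 20) * log(1 - (20 / 19) * p),
         NA_real_)
}

#' Pairwise distance matrix from an alignment
#'
#' @param aln an `aligned_set`.
#' @param correction `"poisson"` (default), `"p"` (no correction), or
#'   `"k20"` (the 20-state uniform-exchange correction); alternatively a
#'   function of `p`.
#' @param min_overlap minimum usable sites per pair.
#' @return A list of class `dist_matrix` with `D` (symmetric matrix,
#'   `NA` where undefined), `n_sites`, and `taxa`.
#' @export
protein_distances <- function(aln, correction = "poisson",
                              min_overlap = 20) {
  fun <- if (is.function(correction)) correction
         else switch(correction,
                     poisson = poisson_distance,
                     p = identity,
                     k20 = k20_distance,
                     stop_invalid("unknown correction: ", correction))
  n <- length(aln$ids)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  NS <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  m <- as.matrix(aln)
  res <- m != "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- res[i, ] & res[j, ]
    ns <- sum(use)
    NS[i, j] <- NS[j, i] <- ns
    if (ns < min_overlap) {
      D[i, j] <- D[j, i] <- NA_real_
    } else {
      p <- sum(m[i, use] != m[j, use]) / ns
      D[i, j] <- D[j, i] <- fun(p)
    }
  }
  structure(list(D = D, n_sites = NS, taxa = aln$ids),
            class = "dist_matrix")
}

#' Neighbor-joining tree
#'
#' The Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined,
#' with branch lengths from the standard split formula.  Q ties are
#' broken lexicographically on the (sorted) taxon-id pair.  A negative
#' estimated branch length is clamped to zero and its deficit moved to
#' the sibling branch, preserving their sum (at the final 3-taxon star,
#' where no sibling pairing exists, negatives are clamped only).
#'
#' @param D symmetric distance matrix with taxon dimnames, or a
#'   `dist_matrix` from [protein_distances()].
#' @return An unrooted `phylo` (the root node is the final trifurcation).
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist_matrix")) D <- D$D
  n <- nrow(D)
  if (is.null(rownames(D))) stop_invalid("distance matrix needs taxon names")
  if (n < 3) stop_invalid("need at least 3 taxa")
  if (anyNA(D)) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    pairs <- apply(bad, 1, function(ix)
      paste(rownames(D)[ix[1]], colnames(D)[ix[2]], sep = "/"))
    stop_invalid("undefined distances for pairs: ",
                 paste(pairs, collapse = ", "))
  }
  frag <- setNames(rownames(D), rownames(D))  # newick fragment per cluster
  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ix)
      paste(sort(c(rownames(D)[ix[1]], rownames(D)[ix[2]])), collapse = "\r"))
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], num_fmt(vi),
                       frag[j], num_fmt(vj))
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nm <- c(rownames(D)[keep], paste0("", rownames(D)[i]))
    dimnames(D2) <- list(nm, nm)
    frag <- c(frag[keep], setNames(newfrag, nm[n - 1]))
    D <- D2
    n <- n - 1
  }
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  x <- pmax(c(x1, x2, x3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], num_fmt(x[1]),
                 frag[2], num_fmt(x[2]), frag[3], num_fmt(x[3]))
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate is rebuilt with the same distance settings and NJ, and the
#' support of an internal edge of the reference tree is the percentage
#' of successful replicates whose tree contains that bipartition.
#' Replicates with undefined distances are skipped and counted; a
#' warning is raised if more than 10% are skipped.
#'
#' @param aln an `aligned_set`.
#' @param n_reps bootstrap replicates (>= 1; the full protocol default
#'   is 1000).
#' @param seed integer seed.
#' @param ref_tree optional reference tree; NJ on the full alignment
#'   when missing.
#' @param correction,min_overlap passed to [protein_distances()].
#' @return A list with `tree` (reference tree, `node.label` set to
#'   supports), `supports` (per internal node), and `n_skipped`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1,
                              ref_tree = NULL, correction = "poisson",
                              min_overlap = 20) {
  if (n_reps < 1) stop_invalid("n_reps must be >= 1")
  if (is.null(ref_tree))
    ref_tree <- neighbor_joining(protein_distances(aln, correction,
                                                   min_overlap))
  m <- as.matrix(aln)
  trees <- list()
  n_skipped <- 0L
  with_seed(op_seed("bootstrap_support", seed), {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      sub <- as_aligned_set(setNames(
        apply(m[, cols, drop = FALSE], 1, paste, collapse = ""), aln$ids))
      Dm <- protein_distances(sub, correction, min_overlap)
      if (anyNA(Dm$D)) {
        n_skipped <- n_skipped + 1L
        next
      }
      trees[[length(trees) + 1L]] <- neighbor_joining(Dm)
    }
  })
  if (n_skipped > 0.1 * n_reps)
    warning(sprintf("%d of %d bootstrap replicates skipped (undefined distances)",
                    n_skipped, n_reps))
  n_used <- length(trees)
  counts <- ape::prop.clades(ref_tree, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- 100 * counts / max(n_used, 1)
  out_tree <- ref_tree
  out_tree$node.label <- num_fmt(supports)
  list(tree = out_tree, supports = supports, n_used = n_used,
       n_skipped = n_skipped)
}

# leaf-set splits induced by each internal edge of an unrooted tree
edge_splits <- function(tree) {
  tipsets <- descendant_tips(tree)
  lapply(seq_len(nrow(tree$edge)), function(i) tipsets[[tree$edge[i, 2]]])
}

#' Root a tree with an outgroup
#'
#' The root is placed at the midpoint of the edge separating the
#' outgroup's most recent common ancestor from the remaining taxa.  If
#' the outgroup is not monophyletic in the unrooted tree, the edge whose
#' split best matches the outgroup set (maximal Jaccard overlap) is used
#' and a warning is emitted.
#'
#' @param tree a `phylo` (typically unrooted, from [neighbor_joining()]).
#' @param outgroup_ids tip labels of the outgroup (a strict subset of
#'   the taxa).
#' @return A rooted binary `phylo`.
#' @export
root_by_outgroup <- function(tree, outgroup_ids) {
  tips <- tree$tip.label
  if (!all(outgroup_ids %in% tips))
    stop_invalid("outgroup ids absent from tree: ",
                 paste(setdiff(outgroup_ids, tips), collapse = ", "))
  if (setequal(outgroup_ids, tips))
    stop_invalid("outgroup cannot contain all taxa")
  og <- sort(unique(outgroup_ids))
  splits <- edge_splits(tree)
  jac <- vapply(splits, function(s) {
    j1 <- length(intersect(s, og)) / length(union(s, og))
    comp <- setdiff(tips, s)
    j2 <- length(intersect(comp, og)) / length(union(comp, og))
    max(j1, j2)
  }, numeric(1))
  best <- which.max(jac)
  if (jac[best] < 1)
    warning("outgroup is not monophyletic; rooting on the edge with ",
            "maximal outgroup purity")
  node <- tree$edge[best, 2]
  len <- tree$edge.length[best]
  rooted <- phytools::reroot(tree, node, position = len / 2)
  rooted
}
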