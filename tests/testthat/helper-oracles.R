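# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive (exhaustive enumeration, closed forms) and share no
# code with the implementation paths they check.

# a small integer scoring scheme for hand-checkable alignments
toy_scheme <- function(match = 1, mismatch = -1, open = -2, extend = -1) {
  m <- matrix(mismatch, 20, 20, dimnames = list(lygfam:::AA20, lygfam:::AA20))
  diag(m) <- match
  scoring_scheme(m, open, extend)
}

# exhaustive-enumeration optimum for global affine-gap alignment:
# depth-first search over all alignment move sequences (match, gap-in-b,
# gap-in-a), scoring runs of gaps as open + len * extend
brute_force_align_score <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  S <- scheme$matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, "M", acc + S[av[i], bv[j]])
    if (i <= length(av))
      rec(i + 1, j, "D", acc + ge + if (prev == "D") 0 else go)
    if (j <= length(bv))
      rec(i, j + 1, "I", acc + ge + if (prev == "I") 0 else go)
  }
  rec(1, 1, "start", 0)
  best
}

# random amino-acid string
random_aa <- function(n) paste(sample(lygfam:::AA20, n, replace = TRUE),
                               collapse = "")

# exhaustive-embedding reconciliation oracle: minimize duplications +
# losses over every valid gene-node -> species-node map (each node maps
# to an ancestor-or-self of its children's maps; leaves fixed)
brute_force_reconcile <- function(gene_tree, species_tree, leaf_map) {
  ntip <- ape::Ntip(gene_tree)
  spar <- lygfam:::node_parents(species_tree)
  sdepth <- lygfam:::node_depths(species_tree)
  gkids <- lygfam:::node_children(gene_tree)
  ancestors_of <- function(v) {
    out <- v
    while (spar[v] != 0L) { v <- spar[v]; out <- c(out, v) }
    out
  }
  is_anc <- function(a, b) a %in% ancestors_of(b)  # a ancestor-or-self of b
  lca2 <- function(a, b) {
    aa <- ancestors_of(a)
    x <- b
    while (!(x %in% aa)) x <- spar[x]
    x
  }
  leafmapnum <- match(leaf_map[gene_tree$tip.label], species_tree$tip.label)
  internal <- ntip + seq_len(gene_tree$Nnode)
  # postorder internal nodes
  po <- ape::reorder.phylo(gene_tree, "postorder")
  ord <- unique(po$edge[, 1])
  best <- list(cost = Inf, dups = NA, losses = NA)
  M <- integer(ntip + gene_tree$Nnode)
  M[seq_len(ntip)] <- leafmapnum
  assign_next <- function(k) {
    if (k > length(ord)) {
      dups <- 0; losses <- 0
      for (v in internal) {
        ch <- gkids[[v]]
        # a node is a speciation only when it sits exactly at the LCA of
        # its children's maps and the children separate into different
        # species subtrees; everything else is a duplication
        isdup <- any(M[ch] == M[v]) || M[v] != lca2(M[ch[1]], M[ch[2]])
        if (isdup) dups <- dups + 1
        for (c2 in ch) {
          d <- sdepth[M[c2]] - sdepth[M[v]]
          losses <- losses + d - 1 + isdup
        }
      }
      cost <- dups + losses
      if (cost < best$cost)
        best <<- list(cost = cost, dups = dups, losses = losses)
      return(invisible())
    }
    v <- ord[k]
    ch <- gkids[[v]]
    base <- lca2(M[ch[1]], M[ch[2]])
    for (cand in ancestors_of(base)) {
      M[v] <<- cand
      assign_next(k + 1)
    }
  }
  assign_next(1)
  best
}

# a random rooted binary gene/species tree pair with a random leaf map
random_recon_instance <- function(n_species = 4, n_genes = 5) {
  st <- ape::rtree(n_species)
  st$tip.label <- paste0("s", seq_len(n_species))
  gt <- ape::rtree(n_genes)
  gt$tip.label <- paste0("g", seq_len(n_genes))
  lm <- setNames(sample(st$tip.label, n_genes, replace = TRUE),
                 gt$tip.label)
  list(gene_tree = gt, species_tree = st, leaf_map = lm)
}

# pair-fraction agreement between two alignments of the same sequences:
# for each column of aln1, the fraction of its residue pairs co-aligned
# in aln2 (columns with < 2 residues count as 1)
pair_fraction <- function(aln1, aln2) {
  m1 <- as.matrix(aln1)
  vapply(seq_len(aln1$width), function(c0) {
    rows <- which(m1[, c0] != "-")
    if (length(rows) < 2) return(1)
    cols2 <- vapply(rows, function(i) {
      id <- aln1$ids[i]
      p <- row_positions(aln1, id)[c0]
      which(row_positions(aln2, id) == p)
    }, integer(1))
    pairs <- utils::combn(seq_along(rows), 2)
    mean(cols2[pairs[1, ]] == cols2[pairs[2, ]])
  }, numeric(1))
}

# hand-built two-species family with exactly one surviving duplication,
# for decay-injection tests
cherry_family <- function() {
  st <- ape::read.tree(text = "(spA:1,spB:1)anc;")
  gt <- ape::read.tree(
    text = "((spA_g1:1,spB_g1:1):0.5,(spA_g2:1,spB_g2:1):0.5)D1;")
  root_seq <- default_root_sequence()
  seqs <- setNames(rep(as.character(root_seq), 4), gt$tip.label)
  lm <- setNames(c("spA", "spB", "spA", "spB"), gt$tip.label)
  fam <- list(species_tree = st, gene_tree = gt,
              events = data.frame(event_id = 1L, kind = "duplication",
                                  species_branch = "anc", time = 0.5,
                                  lineage = 1L, survived = TRUE),
              leaf_map = lm, copy_number = c(spA = 2L, spB = 2L),
              sequences = seqs,
              truth = data.frame(gene = gt$tip.label,
                                 species = unname(lm),
                                 catalytic_intact = TRUE,
                                 signal_peptide = TRUE,
                                 stringsAsFactors = FALSE),
              loci = lygfam:::make_loci(lm),
              config = list(catalytic = attr(root_seq, "catalytic"),
                            signal_len = attr(root_seq, "signal_len")))
  class(fam) <- "simulated_family"
  fam
}
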