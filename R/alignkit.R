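# Progressive protein alignment with perturbation-based column
# confidence.  Needleman-Wunsch global alignment with affine gaps is the
# primitive; a k-mer/UPGMA guide tree orders profile-profile merges; the
# column confidence score follows the alignment-perturbation idea: the
# base alignment is rebuilt under bootstrap-perturbed guide trees and a
# column is scored by how often its residue pairs stay together.

#' Affine-gap scoring scheme
#'
#' @param matrix symmetric substitution matrix over the 20 amino acids;
#'   default is the BLOSUM62 matrix shipped with Biostrings, restricted
#'   to the standard alphabet.
#' @param gap_open gap opening penalty (<= 0).  A gap of length k costs
#'   `gap_open + k * gap_extend`; terminal gaps are penalized exactly
#'   like internal ones.
#' @param gap_extend gap extension penalty (<= 0).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = -10, gap_extend = -1) {
  if (is.null(matrix)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    matrix <- BLOSUM62[AA20, AA20]
  }
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop_invalid("substitution matrix must be symmetric")
  if (gap_open > 0 || gap_extend > 0)
    stop_invalid("gap penalties must be <= 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

check_residues <- function(seq, id, alphabet) {
  v <- chars(seq)
  bad <- which(!(v %in% alphabet))
  if (length(bad))
    stop_invalid("illegal residue '", v[bad[1]], "' at position ", bad[1],
                 " of sequence ", id)
  v
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch over the full sequences; the score is the global
#' optimum under the scheme.  Traceback ties prefer match/mismatch over
#' deletion (gap in `b`) over insertion (gap in `a`), so the result is
#' deterministic.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @return A list with `alignment` (two gapped strings, named `a` and
#'   `b`) and `score`.
#' @export
pairwise_align <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop_invalid("empty input sequence")
  alpha <- rownames(scheme$matrix)
  av <- check_residues(a, "a", alpha)
  bv <- check_residues(b, "b", alpha)
  S <- scheme$matrix[av, bv, drop = FALSE]
  r <- .affine_dp(S, scheme$gap_open, scheme$gap_extend)
  ga <- ifelse(r$a_index == 0, "-", av[pmax(r$a_index, 1)])
  gb <- ifelse(r$b_index == 0, "-", bv[pmax(r$b_index, 1)])
  list(alignment = c(a = paste(ga, collapse = ""),
                     b = paste(gb, collapse = "")),
       score = r$score)
}

# k-mer count matrix over the union vocabulary, rows = sequences
kmer_counts <- function(seqs, k = 3) {
  ids <- names(seqs)
  kms <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  })
  vocab <- sort(unique(unlist(kms)))
  m <- matrix(0, nrow = length(seqs), ncol = length(vocab),
              dimnames = list(ids, vocab))
  for (i in seq_along(kms)) {
    t <- table(kms[[i]])
    m[i, names(t)] <- as.numeric(t)
  }
  m
}

guide_from_counts <- function(counts) {
  d <- dist(counts)
  hc <- hclust(d, method = "average")   # UPGMA
  if (length(labels(d)) == 2) {
    # ape's hclust conversion needs >= 3 leaves; build the cherry directly
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
      labels(d)[1], num_fmt(as.numeric(d) / 2),
      labels(d)[2], num_fmt(as.numeric(d) / 2))))
  }
  ape::as.phylo(hc)
}

#' Build a guide tree for progressive alignment
#'
#' Distances are Euclidean between k-mer (k = 3) count vectors; merge
#' order is UPGMA.  Sequence ids are sorted lexicographically before
#' clustering so that distance ties resolve deterministically.
#'
#' @param seqs named character vector (>= 2 sequences, unique ids).
#' @param k k-mer size.
#' @return A rooted `phylo` giving the merge order.
#' @export
guide_tree <- function(seqs, k = 3) {
  if (length(seqs) < 2) stop_invalid("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_invalid("sequences must have unique ids")
  seqs <- seqs[order(names(seqs))]
  guide_from_counts(kmer_counts(seqs, k))
}

# profile = character matrix, rows = sequences (rownames = ids)
profile_freqs <- function(prof) {
  f <- matrix(0, nrow = length(AA20), ncol = ncol(prof),
              dimnames = list(AA20, NULL))
  n <- nrow(prof)
  for (a in AA20) f[a, ] <- colSums(prof == a) / n
  f
}

align_profiles <- function(p1, p2, scheme) {
  S <- t(profile_freqs(p1)) %*% scheme$matrix %*% profile_freqs(p2)
  r <- .affine_dp(S, scheme$gap_open, scheme$gap_extend)
  w <- length(r$a_index)
  out <- matrix("-", nrow = nrow(p1) + nrow(p2), ncol = w,
                dimnames = list(c(rownames(p1), rownames(p2)), NULL))
  ai <- r$a_index > 0
  bi <- r$b_index > 0
  out[seq_len(nrow(p1)), ai] <- p1[, r$a_index[ai], drop = FALSE]
  out[nrow(p1) + seq_len(nrow(p2)), bi] <- p2[, r$b_index[bi], drop = FALSE]
  out
}

#' Progressive multiple alignment
#'
#' Profile-profile alignment up the guide tree ("once a gap, always a
#' gap").  Profile columns are scored as frequency-weighted sums of
#' substitution scores; gap characters carry zero weight.
#'
#' @param seqs named character vector.
#' @param guide optional guide tree (`phylo` over exactly the input
#'   ids); computed with [guide_tree()] when missing.
#' @param scheme a [scoring_scheme()].
#' @return An `aligned_set` (see [as_aligned_set()]).
#' @export
progressive_align <- function(seqs, guide = NULL, scheme = scoring_scheme()) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_invalid("sequences must have unique ids")
  alpha <- rownames(scheme$matrix)
  for (id in names(seqs)) check_residues(seqs[[id]], id, alpha)
  if (length(seqs) == 1)
    return(as_aligned_set(seqs))
  if (is.null(guide)) guide <- guide_tree(seqs)
  if (!setequal(guide$tip.label, names(seqs)))
    stop_invalid("guide tree ids do not match the input sequences")
  ntip <- ape::Ntip(guide)
  profs <- vector("list", ntip + guide$Nnode)
  for (i in seq_len(ntip)) {
    v <- chars(seqs[[guide$tip.label[i]]])
    profs[[i]] <- matrix(v, nrow = 1,
                         dimnames = list(guide$tip.label[i], NULL))
  }
  po <- ape::reorder.phylo(guide, "postorder")
  for (i in seq(1, nrow(po$edge), by = 2)) {
    a <- po$edge[i, 1]
    b1 <- po$edge[i, 2]; b2 <- po$edge[i + 1, 2]
    profs[[a]] <- align_profiles(profs[[b1]], profs[[b2]], scheme)
  }
  m <- profs[[ntip + 1L]]
  m <- m[names(seqs), , drop = FALSE]  # restore input order
  as_aligned_set(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
}

#' Construct an aligned set
#'
#' The container for a fixed-width gapped alignment: equal-width rows,
#' optional per-column confidence scores in `[0, 1]`, and a map from
#' current columns back to the columns of the alignment they were
#' trimmed from.  De-gapping any row always reproduces the input
#' sequence exactly.
#'
#' @param seqs named character vector of equal-width gapped strings.
#' @param confidence optional numeric vector, one score per column.
#' @param col_origin optional integer vector mapping columns to the
#'   original (pre-trim) alignment columns.
#' @return A list of class `aligned_set` with elements `ids`, `seqs`,
#'   `width`, `confidence`, `col_origin`.
#' @export
as_aligned_set <- function(seqs, confidence = NULL, col_origin = NULL) {
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop_invalid("rows must have equal width")
  if (!is.null(confidence) && length(confidence) != w)
    stop_invalid("confidence vector length must equal the width")
  structure(list(ids = names(seqs), seqs = seqs, width = w,
                 confidence = confidence,
                 col_origin = col_origin %||% seq_len(w)),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned_set: %d sequences x %d columns%s\n",
              length(x$ids), x$width,
              if (is.null(x$confidence)) "" else " (confidence computed)"))
  invisible(x)
}

#' @export
as.matrix.aligned_set <- function(x, ...) {
  do.call(rbind, lapply(x$seqs, chars))
}

#' Remove gaps from alignment rows
#' @param aln an `aligned_set`.
#' @return Named character vector of ungapped sequences.
#' @export
degap <- function(aln) {
  setNames(gsub("-", "", aln$seqs, fixed = TRUE), aln$ids)
}

#' Column to ungapped-position map for one row
#' @param aln an `aligned_set`.
#' @param id row id.
#' @return Integer vector, one entry per column: the 1-based ungapped
#'   position consumed at that column, or `NA` at gaps.
#' @export
row_positions <- function(aln, id) {
  v <- chars(aln$seqs[[id]])
  p <- cumsum(v != "-")
  p[v == "-"] <- NA_integer_
  p
}

#' Perturbation-based column confidence
#'
#' The base alignment is rebuilt under `n_perturb` perturbed guide trees
#' (k-mer count columns resampled with replacement).  A base column's
#' score is the mean, over perturbations, of the fraction of its aligned
#' residue pairs that are placed in a common column of the perturbed
#' alignment.  Columns holding fewer than two residues have no pairs and
#' score 1.
#'
#' @param seqs named character vector of unaligned sequences.
#' @param scheme a [scoring_scheme()].
#' @param n_perturb number of perturbed replicates (>= 1).
#' @param seed integer seed.
#' @param base optional precomputed base alignment for `seqs`.
#' @return The base `aligned_set` with `confidence` filled in.
#' @export
column_confidence <- function(seqs, scheme = scoring_scheme(),
                              n_perturb = 10, seed = 1, base = NULL) {
  if (n_perturb < 1) stop_invalid("n_perturb must be >= 1")
  if (is.null(base)) base <- progressive_align(seqs, scheme = scheme)
  seqs <- degap(base)
  counts <- kmer_counts(seqs[order(names(seqs))])
  basemat <- as.matrix(base)
  pos <- lapply(base$ids, function(id) row_positions(base, id))
  names(pos) <- base$ids

  score_against <- function(aln2) {
    # for each row of the perturbed alignment: ungapped position -> column
    p2c <- lapply(base$ids, function(id) {
      p <- row_positions(aln2, id)
      out <- integer(max(p, na.rm = TRUE))
      out[p[!is.na(p)]] <- which(!is.na(p))
      out
    })
    names(p2c) <- base$ids
    vapply(seq_len(base$width), function(c0) {
      rows <- which(basemat[, c0] != "-")
      if (length(rows) < 2) return(1)
      cols <- vapply(rows, function(i) {
        id <- base$ids[i]
        p2c[[id]][pos[[id]][c0]]
      }, integer(1))
      tb <- table(cols)
      sum(choose(tb, 2)) / choose(length(rows), 2)
    }, numeric(1))
  }

  scores <- with_seed(op_seed("column_confidence", seed), {
    acc <- numeric(base$width)
    for (r in seq_len(n_perturb)) {
      idx <- sample.int(ncol(counts), ncol(counts), replace = TRUE)
      g <- guide_from_counts(counts[, idx, drop = FALSE])
      aln_r <- progressive_align(seqs, guide = g, scheme = scheme)
      acc <- acc + score_against(aln_r)
    }
    acc / n_perturb
  })
  base$confidence <- scores
  base
}

#' Trim low-confidence alignment columns
#'
#' Retains exactly the columns whose confidence score is greater than or
#' equal to `cutoff` (the boundary is kept, so a perfect-confidence
#' alignment survives cutoff 1).  The default cutoff is 0.93.
#'
#' @param aln an `aligned_set` with confidence computed.
#' @param cutoff retention threshold in `[0, 1]`.
#' @return A trimmed `aligned_set`; the removed original column indices
#'   are in its `removed` element and the kept columns' origins in
#'   `col_origin`.
#' @export
trim_alignment <- function(aln, cutoff = 0.93) {
  if (is.null(aln$confidence))
    stop_invalid("confidence scores have not been computed")
  if (cutoff < 0 || cutoff > 1) stop_invalid("cutoff must be in [0, 1]")
  keep <- which(aln$confidence >= cutoff)
  if (length(keep) == 0)
    warning("all columns fall below the cutoff; alignment is empty")
  m <- as.matrix(aln)
  seqs <- setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
                   aln$ids)
  # carry each row's original ungapped positions through the trim, so
  # that reference numbering survives column removal
  orig <- lapply(aln$ids, function(id)
    (aln$orig_positions[[id]] %||% row_positions(aln, id))[keep])
  names(orig) <- aln$ids
  out <- structure(list(ids = aln$ids, seqs = seqs, width = length(keep),
                        confidence = aln$confidence[keep],
                        col_origin = aln$col_origin[keep],
                        orig_positions = orig,
                        removed = setdiff(aln$col_origin, aln$col_origin[keep])),
                   class = "aligned_set")
  out
}

#' Expand a protein alignment to codons
#'
#' Each CDS must translate (standard code) to its protein row, allowing
#' one terminal stop codon.  Residue columns expand to codon triplets and
#' gaps to `---`, so the protein alignment is retained at the nucleotide
#' level.
#'
#' @param protein_aln an `aligned_set` of proteins.
#' @param cds named character vector of coding nucleotide sequences
#'   covering the same ids.
#' @return An `aligned_set` of gapped codon sequences (width tripled).
#' @export
codon_backmap <- function(protein_aln, cds) {
  missing_ids <- setdiff(protein_aln$ids, names(cds))
  if (length(missing_ids))
    stop_invalid("no CDS for: ", paste(missing_ids, collapse = ", "))
  prots <- degap(protein_aln)
  out <- character(length(protein_aln$ids))
  names(out) <- protein_aln$ids
  for (id in protein_aln$ids) {
    p <- prots[[id]]
    s <- cds[[id]]
    if (nchar(s) == 3 * nchar(p) + 3) {
      last <- toupper(substr(s, nchar(s) - 2, nchar(s)))
      if (!last %in% c("TAA", "TAG", "TGA"))
        stop_invalid("CDS of ", id, " has extra length but no terminal stop")
      s <- substr(s, 1, nchar(s) - 3)
    }
    if (nchar(s) != 3 * nchar(p))
      stop_invalid("CDS length of ", id,
                   " is not 3x the protein length (+3 for a stop)")
    tr <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    trv <- chars(tr); pv <- chars(p)
    mis <- which(trv != pv)
    if (length(mis))
      stop_invalid("translation mismatch in ", id, " at residue ", mis[1],
                   ": CDS gives '", trv[mis[1]], "', protein has '",
                   pv[mis[1]], "'")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    av <- chars(protein_aln$seqs[[id]])
    expanded <- character(length(av))
    expanded[av == "-"] <- "---"
    k <- cumsum(av != "-")
    expanded[av != "-"] <- codons[k[av != "-"]]
    out[[id]] <- paste(expanded, collapse = "")
  }
  as_aligned_set(out)
}
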