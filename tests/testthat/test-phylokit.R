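test_that("p-distance uses pairwise deletion", {
  aln <- as_aligned_set(c(a = "AAAA", b = "AAAT", c = "A-AA", d = "ATAA"))
  r <- p_distance(aln, c("a", "b"), min_overlap = 1)
  expect_equal(r$p, 0.25)
  expect_equal(r$n_sites, 4)
  r2 <- p_distance(aln, c("c", "d"), min_overlap = 1)
  expect_equal(r2$n_sites, 3)
  expect_equal(r2$p, 0)
  r3 <- p_distance(aln, c("a", "a"), min_overlap = 1)
  expect_equal(r3$p, 0)
  # overlap below the minimum flags the distance undefined
  r4 <- p_distance(aln, c("a", "b"), min_overlap = 20)
  expect_true(r4$undefined)
  expect_true(is.na(r4$p))
})

test_that("Poisson correction follows the closed form and flags saturation", {
  expect_equal(poisson_distance(0), 0)
  expect_equal(poisson_distance(0.5), log(2))
  expect_true(is.na(poisson_distance(1)))
})

test_that("corrected distances recover the simulating divergence", {
  # two sequences at true distance t = 0.4 under the uniform-exchange
  # model; the 20-state correction is consistent for it
  gt <- ape::read.tree(text = "(x:0.2,y:0.2);")
  L <- 5000
  root <- withr::with_seed(31, random_aa(L))
  seqs <- evolve_sequences(gt, root, rate = 1, seed = 17)
  aln <- as_aligned_set(seqs)
  D <- protein_distances(aln, correction = "k20")
  t <- 0.4
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * t))
  # delta-method SE of the corrected estimate
  se <- sqrt(p_exp * (1 - p_exp) / L) / (1 - (20 / 19) * p_exp)
  expect_lt(abs(D$D["x", "y"] - t), 3 * se)
})

test_that("NJ solves additive matrices exactly", {
  # the classic four-point example
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_equal(max(abs(cophenetic(tr)[rownames(D), colnames(D)] - D)), 0)
  truth <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(ape::dist.topo(tr, ape::unroot(truth)), 0,
               ignore_attr = TRUE)

  # three taxa: closed-form star lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(lens["x"]), (3 + 4 - 5) / 2)
  expect_equal(unname(lens["y"]), (3 + 5 - 4) / 2)
  expect_equal(unname(lens["z"]), (4 + 5 - 3) / 2)

  D[1, 2] <- D[2, 1] <- NA
  expect_error(neighbor_joining(D), "A/B")
})

test_that("NJ recovers random generating topologies from path lengths", {
  withr::with_seed(19, {
    for (i in 1:30) {
      n <- sample(4:8, 1)
      tr <- ape::rtree(n, rooted = FALSE)
      D <- cophenetic(tr)
      nj <- neighbor_joining(D)
      expect_equal(ape::dist.topo(nj, tr), 0, ignore_attr = TRUE)
      expect_lt(max(abs(cophenetic(nj)[rownames(D), colnames(D)] - D)),
                1e-9)
    }
  })
})

test_that("NJ agrees with the reference implementation in ape", {
  fam <- simulate_family(seed = 8)
  aln <- progressive_align(fam$sequences)
  D <- protein_distances(aln, min_overlap = 5)
  mine <- neighbor_joining(D)
  ref <- ape::nj(stats::as.dist(D$D))
  expect_equal(ape::dist.topo(mine, ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap supports behave on signal-free and strong-signal data", {
  same <- setNames(rep("ACDEFGHIKLMNPQRSTVWYACDEF", 4), paste0("t", 1:4))
  aln <- as_aligned_set(same)
  bs <- bootstrap_support(aln, n_reps = 20, seed = 3, min_overlap = 5)
  expect_equal(bs$n_skipped, 0)
  expect_equal(bs$n_used, 20)

  # a long internal branch gives a near-certain bipartition
  st <- ape::read.tree(text = "((a:0.05,b:0.05):0.5,(c:0.05,d:0.05):0.5);")
  root <- withr::with_seed(41, random_aa(500))
  seqs <- evolve_sequences(st, root, rate = 1, seed = 23)
  aln2 <- as_aligned_set(seqs)
  bs2 <- bootstrap_support(aln2, n_reps = 100, seed = 5, min_overlap = 5)
  internal <- which(bs2$tree$edge[, 2] > ape::Ntip(bs2$tree))
  expect_true(any(bs2$supports >= 95))
})

test_that("bootstrap supports are invariant under taxon permutation", {
  fam <- simulate_family(seed = 8)
  seqs <- fam$sequences[1:8]
  aln <- progressive_align(seqs)
  m <- as.matrix(aln)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  aln_p <- as_aligned_set(setNames(apply(m[perm, ], 1, paste, collapse = ""),
                                   aln$ids[perm]))
  b1 <- bootstrap_support(aln, n_reps = 60, seed = 9, min_overlap = 5)
  b2 <- bootstrap_support(aln_p, n_reps = 60, seed = 9, min_overlap = 5)
  key <- function(b) {
    # canonicalize each bipartition by the side holding the first taxon
    all_tips <- sort(b$tree$tip.label)
    sets <- lygfam:::descendant_tips(b$tree)
    ntip <- ape::Ntip(b$tree)
    idx <- (ntip + 1):(ntip + b$tree$Nnode)
    s <- vapply(sets[idx], function(side) {
      if (!(all_tips[1] %in% side)) side <- setdiff(all_tips, side)
      paste(sort(side), collapse = "+")
    }, "")
    v <- setNames(b$supports, s)
    v[order(names(v))]
  }
  expect_equal(key(b1), key(b2))
})

test_that("outgroup rooting places and round-trips the root", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,(d:1,e:1):1):1);")
  tru <- ape::unroot(tr)
  rooted <- root_by_outgroup(tru, "a")
  expect_true(ape::is.rooted(rooted))
  kids <- lygfam:::node_children(rooted)[[ape::Ntip(rooted) + 1]]
  sides <- lygfam:::descendant_tips(rooted)[kids]
  expect_true(list("a") %in% sides)
  expect_equal(ape::dist.topo(ape::unroot(rooted), tru), 0,
               ignore_attr = TRUE)

  expect_error(root_by_outgroup(tru, letters[1:5]), "all taxa")
  expect_error(root_by_outgroup(tru, "zz"), "absent")
  # non-monophyletic outgroup warns
  expect_warning(root_by_outgroup(tru, c("a", "c")), "not monophyletic")
})

test_that("rooting a simulated family separates the true ingroup", {
  for (s in c(2, 6)) {
    sim <- simulate_gene_family(vertebrate_tree(), 0.2, 0.05, seed = s)
    og <- names(sim$leaf_map)[sim$leaf_map == "lamprey"]
    if (length(og) == 0 || length(og) == length(sim$leaf_map)) next
    un <- ape::unroot(sim$gene_tree)
    rooted <- suppressWarnings(root_by_outgroup(un, og))
    kids <- lygfam:::node_children(rooted)[[ape::Ntip(rooted) + 1]]
    sides <- lygfam:::descendant_tips(rooted)[kids]
    ing <- sort(setdiff(sim$gene_tree$tip.label, og))
    expect_true(any(vapply(sides, identical, logical(1), y = ing)))
  }
})
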