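toy_species <- ape::read.tree(
  text = "((mouse:1,rat:1)murine_ancestor:2,chicken:3)amniote_ancestor;")

test_that("congruent gene trees reconcile with no events", {
  gt <- ape::read.tree(text = "((mouse_1:1,rat_1:1):2,chicken_1:3);")
  lm <- setNames(c("mouse", "rat", "chicken"), gt$tip.label)
  rec <- lca_reconcile(gt, toy_species, lm)
  expect_length(rec$dup_nodes, 0)
  expect_equal(rec$losses_total, 0)
  expect_true(all(count_losses_per_lineage(rec)$losses == 0))
})

test_that("an ancestral duplication with full retention is placed on the ancestor", {
  # two paralogs retained in both descendant species: one duplication at
  # their common ancestor, no losses
  st <- ape::read.tree(text = "(sp1:1,sp2:1)anc;")
  gt <- ape::read.tree(
    text = "((sp1_gA1:1,sp2_gA1:1):0.5,(sp1_gA2:1,sp2_gA2:1):0.5);")
  lm <- setNames(c("sp1", "sp2", "sp1", "sp2"), gt$tip.label)
  rec <- lca_reconcile(gt, st, lm)
  expect_length(rec$dup_nodes, 1)
  expect_equal(rec$losses_total, 0)
  lab <- label_duplication_ages(rec)
  expect_equal(lab$label, "anc")
})

test_that("differential paralog loss lands on the right branch", {
  # three amniote paralogs, two of them lost on the mammal stem: the
  # reconciliation must put 2 losses on the branch to the mammal clade
  st <- ape::read.tree(
    text = "((mouse:1,rat:1)murine_ancestor:2,(chicken:2,turkey:2)bird_ancestor:1)amniote_ancestor;")
  gt <- ape::read.tree(text = paste0(
    "((((mouse_A:1,rat_A:1):2,(chicken_A:2,turkey_A:2):1):0.2,",
    "(chicken_B:2,turkey_B:2):1.2):0.1,(chicken_C:2,turkey_C:2):1.3);"))
  lm <- setNames(sub("_.*$", "", gt$tip.label), gt$tip.label)
  rec <- lca_reconcile(gt, st, lm)
  expect_length(rec$dup_nodes, 2)
  losses <- count_losses_per_lineage(rec)
  expect_equal(losses$losses[losses$branch == "murine_ancestor"], 2)
  expect_equal(rec$losses_total, 2)
})

test_that("duplication and loss counts equal the exhaustive-embedding oracle", {
  withr::with_seed(23, {
    for (i in 1:40) {
      inst <- random_recon_instance(sample(3:5, 1), sample(3:6, 1))
      rec <- lca_reconcile(inst$gene_tree, inst$species_tree, inst$leaf_map)
      oracle <- brute_force_reconcile(inst$gene_tree, inst$species_tree,
                                      inst$leaf_map)
      expect_equal(length(rec$dup_nodes), oracle$dups)
      expect_equal(rec$losses_total, oracle$losses)
      # branch decomposition sums to the total
      expect_equal(sum(count_losses_per_lineage(rec)$losses),
                   rec$losses_total)
    }
  })
})

test_that("reconciliation validates its inputs", {
  gt <- ape::read.tree(text = "((mouse_1:1,rat_1:1):2,chicken_1:3);")
  expect_error(lca_reconcile(gt, toy_species, c(mouse_1 = "mouse")),
               "missing from leaf map")
  lm <- setNames(c("mouse", "rat", "dog"), gt$tip.label)
  expect_error(lca_reconcile(gt, toy_species, lm), "absent from species tree")
})

test_that("nested duplications on one ancestor are reported as an ordered series", {
  st2 <- ape::read.tree(text = "((human:3,chicken:3)amniote_ancestor:1,fish:4)root_anc;")
  gt2 <- ape::read.tree(text = paste0(
    "((((h1:3,c1:3):0.4,(h2:3,c2:3):0.4):0.3,(h3:3,c3:3):0.7):1,f1:4.7);"))
  lm2 <- setNames(c("human", "chicken", "human", "chicken", "human",
                    "chicken", "fish"),
                  c("h1", "c1", "h2", "c2", "h3", "c3", "f1"))
  rec <- lca_reconcile(gt2, st2, lm2)
  lab <- label_duplication_ages(rec)
  amn <- lab[lab$label == "amniote_ancestor", ]
  expect_equal(nrow(amn), 2)
  expect_equal(sort(amn$series_rank), 1:2)
  expect_true(all(amn$n_in_series == 2))
  # the rank-1 event is the gene-tree ancestor of the rank-2 event
  shallow <- amn$node[amn$series_rank == 1]
  deep <- amn$node[amn$series_rank == 2]
  expect_true(shallow %in% lygfam:::node_parents(gt2)[deep] ||
                deep %in% unlist(lygfam:::descendant_tips(gt2)[shallow]) ||
                lygfam:::node_depths(gt2)[shallow] <
                  lygfam:::node_depths(gt2)[deep])
  # custom display names are honored
  lab2 <- label_duplication_ages(rec,
                                 c(amniote_ancestor = "amniote ancestor"))
  expect_true(all(lab2$label[lab2$species_node ==
                               amn$species_node[1]] == "amniote ancestor"))
})

test_that("paralog naming reproduces the published tier conventions", {
  # amniote-level triplication: letters by decreasing clade size
  st2 <- ape::read.tree(text = "((human:3,chicken:3)amniote_ancestor:1,fish:4)root_anc;")
  gt2 <- ape::read.tree(text = paste0(
    "((((h1:3,c1:3):0.4,(h2:3,c2:3):0.4):0.3,(h3:3,c3:3):0.7):1,f1:4.7);"))
  lm2 <- setNames(c("human", "chicken", "human", "chicken", "human",
                    "chicken", "fish"),
                  c("h1", "c1", "h2", "c2", "h3", "c3", "f1"))
  nm <- assign_names(lca_reconcile(gt2, st2, lm2), "Lyg")
  expect_setequal(nm$name[nm$gene %in% c("h1", "c1")], "LygA")
  expect_setequal(nm$name[nm$gene %in% c("h2", "c2")], "LygB")
  expect_setequal(nm$name[nm$gene %in% c("h3", "c3")], "LygC")
  expect_equal(nm$name[nm$gene == "f1"], "Lyg")

  # single-copy family: bare prefix
  gt1 <- ape::read.tree(text = "((mouse_1:1,rat_1:1):2,chicken_1:3);")
  lm1 <- setNames(c("mouse", "rat", "chicken"), gt1$tip.label)
  nm1 <- assign_names(lca_reconcile(gt1, toy_species, lm1), "Lyg")
  expect_true(all(nm1$name == "Lyg"))

  # rat-like segmental pattern: ancient letter, mammalian number,
  # species-specific trailing letters
  gtr <- ape::read.tree(text = paste0(
    "(((((rat_x1:0.1,rat_x2:0.1):0.9,mouse_x:1):2,",
    "((rat_y1:0.1,rat_y2:0.1):0.9,mouse_y:1):2):0.8,chicken_a:3):0.1,",
    "chicken_b:3.1);"))
  lmr <- setNames(c("rat", "rat", "mouse", "rat", "rat", "mouse",
                    "chicken", "chicken"),
                  c("rat_x1", "rat_x2", "mouse_x", "rat_y1", "rat_y2",
                    "mouse_y", "chicken_a", "chicken_b"))
  nmr <- assign_names(lca_reconcile(gtr, toy_species, lmr), "Lyg")
  got <- setNames(nmr$name, nmr$gene)
  expect_setequal(unname(got[c("rat_x1", "rat_x2")]), c("LygA1a", "LygA1b"))
  expect_setequal(unname(got[c("rat_y1", "rat_y2")]), c("LygA2a", "LygA2b"))
  expect_setequal(unname(got[c("mouse_x", "mouse_y")]), c("LygA1", "LygA2"))
  expect_equal(unname(got["chicken_a"]), "LygA")
  expect_equal(unname(got["chicken_b"]), "LygB")

  # within-species duplicates without a number tier get plain numbers
  gtz <- ape::read.tree(text = paste0(
    "(((rat_a:0.1,(rat_b:0.05,rat_c:0.05):0.05):0.9,mouse_1:1):2,",
    "chicken_1:3);"))
  lmz <- setNames(c("rat", "rat", "rat", "mouse", "chicken"),
                  c("rat_a", "rat_b", "rat_c", "mouse_1", "chicken_1"))
  nmz <- assign_names(lca_reconcile(gtz, toy_species, lmz), "Lyg")
  expect_setequal(nmz$name[nmz$species == "rat"],
                  c("Lyg1", "Lyg2", "Lyg3"))
})

test_that("naming is invariant under leaf-order permutation", {
  sim <- simulate_gene_family(vertebrate_tree(), 0.3, 0.05, seed = 12)
  rec <- lca_reconcile(sim$gene_tree, vertebrate_tree(), sim$leaf_map)
  nm <- assign_names(rec)
  gt2 <- ape::rotateConstr(sim$gene_tree, sample(sim$gene_tree$tip.label))
  rec2 <- lca_reconcile(gt2, vertebrate_tree(), sim$leaf_map)
  nm2 <- assign_names(rec2)
  expect_equal(setNames(nm$name, nm$gene)[sort(nm$gene)],
               setNames(nm2$name, nm2$gene)[sort(nm$gene)])
})

test_that("called duplications are sound against simulated truth", {
  # every called duplication is a true surviving duplication, and its
  # label is never older than the true branch (LCA maps can only shift
  # an age toward the leaves when losses hide one side)
  st <- vertebrate_tree()
  spar <- lygfam:::node_parents(st)
  stip <- lygfam:::descendant_tips(st)
  name_of <- vapply(seq_along(spar),
                    function(v) lygfam:::species_node_name(st, v, stip), "")
  for (s in 1:25) {
    sim <- simulate_gene_family(st, 0.2, 0.05, seed = s)
    if (is.null(sim$gene_tree)) next
    rec <- lca_reconcile(sim$gene_tree, st, sim$leaf_map)
    lab <- label_duplication_ages(rec)
    gl <- sim$gene_tree$node.label
    dup_idx <- which(grepl("^D", gl)) + ape::Ntip(sim$gene_tree)
    # called duplications are exactly gene-tree nodes labelled as true
    # surviving duplications, possibly minus blindness cases
    expect_true(all(rec$dup_nodes %in% dup_idx))
    ev <- sim$events[sim$events$kind == "duplication" &
                       sim$events$survived %in% TRUE, ]
    for (k in seq_along(rec$dup_nodes)) {
      v <- rec$dup_nodes[k]
      id <- as.integer(sub("^D", "", gl[v - ape::Ntip(sim$gene_tree)]))
      true_branch <- ev$species_branch[ev$event_id == id]
      called_node <- rec$map[v]
      true_node <- which(name_of == true_branch)
      # called node must be the true node or one of its descendants
      anc <- called_node
      while (anc != 0 && anc != true_node) anc <- spar[anc]
      expect_equal(anc, true_node)
    }
  }
})
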