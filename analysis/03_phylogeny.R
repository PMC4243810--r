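#!/usr/bin/env Rscript
# Step 3: neighbor-joining phylogeny with bootstrap and outgroup
# rooting.
#
# Poisson-corrected pairwise-deletion distances feed Saitou-Nei NJ; the
# protocol's 1000 column-bootstrap replicates give internal-edge
# supports; the tree is rooted with the lamprey genes (the jawless-fish
# outgroup) and the outgroup is dropped for downstream reconciliation.

suppressMessages(library(lygfam))

fam <- read_fixture("results/fixture")
trimmed <- as_aligned_set(read_fasta("results/trimmed.fasta"))

D <- protein_distances(trimmed, min_overlap = 20)
write_phylip_dist(D, "results/distances.phylip")

bs <- bootstrap_support(trimmed, n_reps = 1000, seed = 42)
ape::write.tree(bs$tree, "results/gene_tree.nwk")
message(sprintf("NJ tree built; %d/%d bootstrap replicates used, %d skipped",
                bs$n_used, 1000, bs$n_skipped))

og <- names(fam$leaf_map)[fam$leaf_map == "lamprey"]
rooted <- root_by_outgroup(bs$tree, og)
ape::write.tree(rooted, "results/rooted_tree.nwk")

# how close is the inferred tree to the true one?
ing <- ape::drop.tip(rooted, og)
true_ing <- ape::drop.tip(fam$gene_tree, og)
rf <- ape::dist.topo(ape::unroot(ing), ape::unroot(true_ing))
message(sprintf("rooted on %d lamprey gene(s); RF distance to the true ingroup tree: %d",
                length(og), rf))
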