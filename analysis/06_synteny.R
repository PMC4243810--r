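#!/usr/bin/env Rscript
# Step 6: synteny neighborhoods and tandem clusters.
#
# For each family gene the 3 nearest non-family neighbors on each side
# are collected, all cross-species neighborhood pairs are scored with
# the Jaccard index over flanking gene symbols, and family genes within
# 200 kb of each other on one scaffold are chained into tandem clusters.

suppressMessages(library(lygfam))

fam <- read_fixture("results/fixture")
loci <- read_loci("results/fixture/loci.tsv")
fam_symbols <- names(fam$leaf_map)

nbhd <- extract_neighborhood(loci, fam_symbols, k = 3)
ids <- names(nbhd)
pairs <- utils::combn(ids, 2)
scores <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
  cs <- conservation_score(nbhd[[pairs[1, i]]], nbhd[[pairs[2, i]]])
  data.frame(gene1 = pairs[1, i], gene2 = pairs[2, i], score = cs$score,
             shared = paste(cs$shared, collapse = ","),
             stringsAsFactors = FALSE)
}))
write_tsv(scores, "results/synteny_scores.tsv")

clusters <- tandem_clusters(loci, fam_symbols, max_gap = 200000)
write_tsv(clusters, "results/clusters.tsv")

message(sprintf("neighborhoods for %d genes; mean cross-gene conservation %.2f",
                length(nbhd), mean(scores$score)))
message(sprintf("%d tandem clusters; sizes: %s; all same-strand: %s",
                nrow(clusters),
                paste(sort(clusters$size, decreasing = TRUE), collapse = ","),
                all(clusters$same_strand)))
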