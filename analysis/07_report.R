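#!/usr/bin/env Rscript
# Step 7: the same analysis end to end through the one-call pipeline.
#
# run_pipeline() replays steps 2-6 from the fixture under a single
# config (with the full 1000-replicate bootstrap) and writes every
# intermediate artifact plus a summary report under results/pipeline/.
# Running it twice with the same config produces byte-identical files.

suppressMessages(library(lygfam))

fam <- read_fixture("results/fixture")
ref <- fam$truth$gene[fam$truth$catalytic_intact & fam$truth$signal_peptide][1]
cfg <- pipeline_config(
  sequences = "results/fixture/sequences.fasta",
  species_tree = "results/fixture/species_tree.nwk",
  leaf_map = "results/fixture/leaf_map.tsv",
  loci = "results/fixture/loci.tsv",
  annotations = "results/fixture/annotations.tsv",
  out_dir = "results/pipeline",
  outgroup = "lamprey",
  reference_id = ref,
  mature_offset = fam$config$signal_len,
  seed = 42)
write_config(cfg, "results/pipeline_config.yaml")

res <- run_pipeline(cfg)
message("summary report:")
str(res$report)
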