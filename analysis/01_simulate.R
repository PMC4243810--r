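#!/usr/bin/env Rscript
# Step 1: generate the ground-truthed study family.
#
# A gene family is simulated along the fixed vertebrate species tree
# under the default study conditions (duplication 0.2 and loss 0.05 per
# lineage per time unit, 0.15 substitutions/site/time, conserved
# catalytic triple, post-duplication decay at probability 0.5 for both
# catalytic knockouts and signal-peptide loss).  The fixture - FASTA,
# Newick, and the truth tables every later step is checked against - is
# written under results/fixture/.

suppressMessages(library(lygfam))

seed <- 42
fam <- simulate_family(seed = seed)
write_fixture(fam, "results/fixture")

surv <- subset(fam$events, kind == "duplication" & survived %in% TRUE)
message(sprintf("simulated %d genes in %d species (seed %d)",
                length(fam$sequences), sum(fam$copy_number > 0), seed))
message(sprintf("true events: %d duplications (%d surviving), %d losses",
                sum(fam$events$kind == "duplication"), nrow(surv),
                sum(fam$events$kind == "loss")))
message(sprintf("true functional decay: %d/%d catalytic knockouts, %d signal-peptide losses",
                sum(!fam$truth$catalytic_intact), nrow(fam$truth),
                sum(!fam$truth$signal_peptide)))
message("per-species copy number:")
print(fam$copy_number)
message("fixture written to results/fixture/")
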