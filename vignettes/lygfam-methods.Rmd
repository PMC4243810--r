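---
title: "Models and methods behind lygfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lygfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lygfam)
```

# The problem

Goose-type lysozyme (lysozyme g) is an antibacterial muramidase found
across vertebrates. Its gene family mixes ancient amplification events
(in the amniote ancestor, on the early mammalian stem, and in an early
teleost lineage) with many recent tandem duplications, and repeated
post-duplication degradation: duplicate copies lose the catalytic
glutamate at mature position 73 or the aspartates at 86/97, or lose
their signal peptide, while the species involved retain at least one
intact, secreted copy. `lygfam` implements the complete analysis chain
needed to characterize such a family — alignment, reliability trimming,
distance phylogeny, gene-tree/species-tree reconciliation with paralog
naming, active-site and secretion scanning with a compensation
cross-tab, and synteny/tandem-cluster analysis — together with a
birth–death simulator that generates families with recorded ground
truth, so that every inference step is testable without external data.

# The simulator

`simulate_gene_family()` runs a linear birth–death process
independently for every gene lineage along every branch of a rooted
ultrametric species tree, starting from one gene at the root.
Duplication (rate $\lambda$) inserts a sister lineage at the event
time; loss (rate $\mu$) terminates the lineage; at speciation nodes all
surviving lineages are copied into both daughters. Under this process
the expected copy number per species is $e^{(\lambda-\mu)T}$ for
root-to-tip depth $T$, which the test suite checks by Monte Carlo. The
returned gene tree keeps only lineages with extant descendants; the
event history also records events inside fully pruned clades, which is
what lets the tests quantify how much of the true history
reconciliation can possibly see.

Study conditions are fixed by the generator defaults: the packaged
14-species vertebrate tree (root depth 5 time units, named ancestors
such as `amniote_ancestor`), $\lambda = 0.2$ and $\mu = 0.05$ per
lineage per time unit, and 0.15 substitutions/site/time. No empirical
duplication/loss rates exist for this family, so the rates are
calibration choices producing realistic families (roughly 1–3 copies
per species with occasional larger expansions), not inferences.

Sequences evolve by an independent-site uniform 20-state exchange
model: events arrive at rate $(20/19)\,r$ per site and resample the
site uniformly, so the expected number of realized substitutions per
site per time is $r$ and the proportion of differing sites at path
length $t$ has the closed form $p = \frac{19}{20}(1 - e^{-20t/19})$.
This oracle-friendly default is deliberate — it makes distance recovery
exactly checkable — and the substitution matrix used for *alignment
scoring* is independent of it. The default root sequence is a
205-residue precursor: a 20-residue hydrophobic signal peptide plus a
185-residue mature region with E at mature 73 and D at 86 and 97,
mirroring the mature-goose coordinate system. The catalytic sites are
fully conserved by default (`conserved_rate_factor = 0`), so any
catalytic change in a simulated family is an injected decay event and
truth tables are exact.

`inject_functional_decay()` emulates post-duplication
subfunctionalization: for each surviving duplication, one randomly
chosen daughter clade receives catalytic knockouts (E→Q at the site-73
analog, D→N at 86/97) with probability 0.5 and/or loses its
signal-peptide prefix with probability 0.5, the sibling staying intact.
Catalytic decay additionally respects essentiality: a clade is degraded
only if every species in it keeps an intact copy outside the clade
(first the drawn daughter is tried, then the sibling, else the knockout
is skipped). This constraint is what guarantees the compensation
pattern — every species with a degraded copy retains an intact one —
exactly, in every replicate. Signal-peptide loss is unconstrained,
since whole lineages can plausibly lose secretion. Gene coordinates
place all copies of a species on one scaffold, same strand, 30 kb
apart, flanked by conserved marker genes (`TXNDC9`/`MRPL30` innermost),
mirroring the tandem layout of the human pair.

Every stochastic operation draws from its own stream, seeded by a hash
of the operation name mixed with the user seed (`op_seed()`), so adding
an operation never perturbs another's draws and all results are
bit-reproducible.

# Alignment and column confidence

`pairwise_align()` is textbook global Needleman–Wunsch with affine gaps
in three-state (M/Ix/Iy) dynamic programming; a gap of length $k$ costs
`gap_open + k * gap_extend`, terminal gaps are penalized like internal
ones, and traceback ties prefer match over deletion over insertion, so
results are deterministic. The default matrix is BLOSUM62 with
open −10 / extend −1. `progressive_align()` aligns profiles up a
guide tree (Euclidean distances between 3-mer count vectors, UPGMA
merge order, ids sorted lexicographically before clustering so ties are
deterministic); profile columns score as frequency-weighted sums of
substitution scores with gaps carrying zero weight, and gaps once
introduced are never removed.

Column reliability follows the alignment-perturbation idea behind
guide-tree-bootstrap confidence scoring: the alignment is rebuilt under
`n_perturb` guide trees computed from k-mer count columns resampled
with replacement, and a base column's score is the mean fraction of its
aligned residue pairs that co-occur in a perturbed alignment. Columns
with fewer than two residues have no pairs and are defined to score
1.0. `trim_alignment()` keeps columns with score ≥ cutoff; the default
cutoff is 0.93. The boundary is kept deliberately so that a
perfect-confidence alignment survives a cutoff of 1. Trimming carries
each row's *original* ungapped positions along, so reference numbering
(below) is unaffected by removed columns. Coordinates are 0-based
internally and 1-based inclusive in all files.

# Distances, NJ, bootstrap, rooting

Distances use pairwise deletion (only columns where both rows carry
residues) with a minimum usable overlap of 20 sites, below which the
pair is flagged undefined — this avoids wild corrections on tiny
overlaps. The shipped correction is the Poisson distance
$d = -\ln(1-p)$, with the plain $p$-distance and the 20-state
correction $d = -\tfrac{19}{20}\ln(1-\tfrac{20}{19}p)$ selectable and
the correction pluggable as a function. The Poisson default replaces
empirical-matrix distances for analytic verifiability; the choice
affects branch lengths far more than topology.

`neighbor_joining()` implements the Saitou–Nei criterion with two
stated conventions: Q-ties break lexicographically on the sorted taxon
pair, and a negative estimated branch length is clamped to zero with
the deficit moved to its sibling so their sum is preserved (at the
final three-taxon star, where no sibling pairing exists, negatives are
clamped only). On any exactly additive matrix the algorithm provably
recovers the generating topology and path lengths, which the tests
assert to 1e−9. Bootstrap resamples alignment columns, rebuilds each
replicate end-to-end, and reports for each internal edge of the
reference tree the percentage of successful replicates containing that
bipartition; replicates with undefined distances are skipped, counted,
and warned about above 10%. The full-protocol default is 1000
replicates. Rooting places the root at the midpoint of the edge whose
split best matches the outgroup (Jaccard overlap), warning when the
outgroup is not monophyletic; support values are not transferred across
rerooting, so edge supports should be read off the unrooted tree.

# Reconciliation, ages, losses, names

`lca_reconcile()` computes the standard last-common-ancestor map in one
postorder pass: a gene node is a duplication iff it maps to the same
species node as one of its children; losses along a gene-tree edge are
the number of skipped species-tree edges, minus one at speciations,
and are attributed to the species branch on which each lineage failed
to survive, so the per-branch table sums exactly to the total. The
brute-force check in the tests minimizes duplications + losses over
*all* valid embeddings and agrees with the LCA map on every random
instance.

Duplication ages are the names of the species nodes the events map to
(`amniote_ancestor`-style labels, or generated `anc(...)` signatures).
Two duplications mapping to the same ancestor that are nested in the
gene tree — the situation of the amniote double event, whose order the
gene tree cannot resolve against the species tree — are reported as an
ordered series with ranks following gene-tree ancestry, rather than
asserted as resolved.

Naming is deterministic and tiered. Clades descending from duplications
whose mapped ancestor is at least `letter_min_age` old (default: half
the species-tree height, which on the packaged tree separates the
amniote event from the mammalian one) receive capital letters, ordered
by decreasing clade size with ties broken by the earliest leaf id;
younger duplications mapping to internal species nodes yield numeric
components with the same ordering; within-species duplicates get
trailing letters when a number is already present (the rat
`A1a`/`A1b` pattern) and plain numbers otherwise (the zebrafish
`1`/`2`/`3` pattern). Letters and numbers are conveniences, not
orthology claims across clades.

A known, quantified limitation: with losses, LCA reconciliation is
blind to part of the true history. A duplication both of whose
daughters survive only in disjoint species subtrees is mapped as a
speciation, and complementary losses can shift an age label toward the
leaves (never away from them). On the default study conditions this
affects roughly 0.2–0.3% of surviving duplications (about 2% of
simulated families contain one such case), a rate the acceptance script
reports as `duplication_label_recovery_pct`. Duplications whose
descendants were entirely lost are invisible by construction.
`collapse_weak_edges()` is provided for robustness runs that collapse
poorly supported edges before interpretation.

# Functional scanning

`build_reference_map()` projects every row onto mature reference
numbering: mature position $p$ is ungapped reference position
$p + \texttt{mature\_offset}$. The offset (the precursor length before
mature position 1, e.g. the signal peptide) is always supplied, never
guessed, because precursor/mature confusion is the main off-by-$k$
hazard in site bookkeeping. Rows report a residue, `gap` (internal
gap), or `missing` (row ends before the region).

`classify_catalytic()` applies mutagenesis-anchored rules in order:
E/D/D is intact; glutamine at 73 is a verified knockout and aspartate a
verified strong reduction; other non-glutamate residues at 73 (lysine,
glycine, …) are graded abolished but marked as inferred, untested
replacements; with E at 73, one replaced aspartate reduces and both
replaced abolish activity. Any required site in a gap/missing state
yields `unknown` — when site 73 already decides the verdict, the
aspartate states are not required. Replacement counts in
`compensation_table()` include observed residues only; gap/missing
states are tallied separately, since replacement statistics should not
count absent data as change. The cross-tab flags species with at least
one non-intact copy and no intact copy.

Secretion verdicts follow imported external predictions when present
(signal peptide yes → classical; otherwise a non-classical secretion
score ≥ 0.5 → possibly non-classical; else intracellular). Without
annotations a crude fallback applies — an 8-residue window in positions
1–30 with mean Kyte–Doolittle hydropathy ≥ 1.6 calls classical — and
the verdict is marked `heuristic, low confidence`. Heuristic calls are
a stand-in for real predictor output and are never a substitute for it
in headline statistics.

# Synteny

Neighborhoods collect the `k = 3` nearest non-family genes on each side
of each family locus on its scaffold. Conservation is the Jaccard index
over case-insensitive flanking symbol sets: a membership measure, which
matches how neighborhood conservation arguments are actually made
(shared flankers like `TXNDC9`/`MRPL30`), rather than an
order-sensitive adjacency score; the ordered variant was considered and
deferred, and reports label the Jaccard formalization as the package's
own. Tandem clustering chains family genes on one scaffold whenever the
intergenic gap (`next.start − prev.end − 1`, 1-based inclusive
coordinates) is at most `max_gap = 200` kb — generous margin around the
~30 kb spacing of the human-type pair — and reports size, span, and
strand agreement. Growing `max_gap` can only merge clusters.

# Pipeline and reproducibility

`run_pipeline()` chains align → confidence → trim → distances → NJ +
bootstrap → outgroup rooting → reconciliation → functional scan →
synteny, persisting every intermediate artifact as plain text (aligned
FASTA, Newick, TSV, a YAML report with the config hash and seed) so
stages are independently inspectable; numbers are written with a fixed
12-significant-digit format, making reruns under one config
byte-identical. Outgroup genes root the tree and are then dropped, and
the outgroup species is removed from the species tree before
reconciliation. The defaults carry the protocol constants (trim cutoff
0.93, 1000 bootstrap replicates). The numbered scripts under
`analysis/` run the same chain step by step on a seeded simulated
family and write their tables under `results/`.

# What the synthetic data do and do not show

The simulator reproduces the statistical structure the analysis
assumes: duplication/loss along a known species tree, site-independent
substitution with conserved catalytic positions, decay confined to
duplication daughters with guaranteed within-species compensation, and
tandem gene placement with conserved flankers. It does not emulate
alignment-relevant indel evolution (the only indel is whole-prefix
signal loss), rate heterogeneity across sites or lineages, codon-level
selection, pseudogenization, assembly artifacts, or incomplete
lineage sorting. Green tests therefore certify the correctness of the
implementations and the internal consistency of the inference chain
under the model's assumptions — not that real families satisfy those
assumptions. Problem sizes in the tests (families of ~20–35 genes,
sequences of 205 residues, 200–1000 replicates for Monte-Carlo checks,
40–100 bootstrap replicates inside end-to-end tests versus 1000 in the
protocol default) were chosen to exercise every code path at desk
scale.
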