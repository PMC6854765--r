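---
title: "Reconstructing gain and loss in the apolipoprotein family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gain and loss in the apolipoprotein family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoevol)
```

## The problem

The exchangeable apolipoproteins — ApoA-I, ApoA-II, ApoA-IV, ApoA-V, the
four ApoC proteins plus the primate-specific acidic variant ApoC-IA, and
ApoE — form a multigene family with a shared modular gene structure. Not
every vertebrate carries every member: some members are ancient and
ubiquitous, others arose at particular speciation nodes and disappeared
again in particular lineages. Given (i) candidate proteomes, (ii) a rooted
species tree, and (iii) a human query panel, the package answers: *which
species has which member, where on the tree was each member gained, where
was it lost, and in what order did the members emerge?*

## The Dollo model and its reconstruction

A family member is modeled as a binary character on the species tree
under **Dollo parsimony**: gained at most once, lost arbitrarily often.
This matches the biology — independent re-invention of a specific
apolipoprotein is vastly less likely than repeated loss, and every member
here is assigned a single origin plus lineage losses.

For a character possessed by leaf set $P$:

* If $P$ is empty, there is no scenario (no gain, no losses).
* If $P$ is all leaves, the gain is assigned the sentinel `PRE_ROOT`:
  the origin predates the tree's root and cannot be placed on any branch.
  Such characters are excluded from the default gain-event count, since
  no event on the sampled tree is implied.
* Otherwise the gain sits on the branch subtending $\mathrm{MRCA}(P)$,
  and one loss is placed on each maximal subtree below the gain node that
  contains no possessing leaf.

This placement minimizes the number of losses among all single-gain
explanations: moving the gain below $\mathrm{MRCA}(P)$ strands a
possessing leaf, and moving it higher can only add empty subtrees. The
test suite verifies the optimality claim against an exhaustive search
over every feasible gain placement on hundreds of random trees, rather
than trusting the argument above.

**Unknown states.** A cell may be `unknown` (unscored rather than
absent). Unknowns are treated as absences when locating the gain node —
they contribute no evidence of presence — but a maximal empty subtree
consisting *entirely* of unknowns generates no loss event: missing
annotation is not evidence of loss. Each scenario records this policy
tag. The packaged fixture does not use the unknown state; the machinery
exists for real, incompletely annotated data.

**Emergence order.** Characters are grouped by gain node and groups are
sorted by the node's depth (edges from the root), `PRE_ROOT` first. Two
groups whose gain nodes share a depth are merged and reported as
simultaneous: a tree provides no ordering between equally deep nodes, and
paired emergences (ApoC-I with ApoC-II) are a real feature of the data.
Characters present nowhere are omitted — they have no origin to rank.

## The curated fixture

`apo_fixture()` returns a 30-species × 10-member presence/absence matrix
and a ladder (pectinate) species tree labeled with clade names. The
species are representatives chosen per clade — 1 cartilaginous fish, the
spotted gar, 4 teleosts, the coelacanth, a frog, 5 saurians of which 3
are birds, platypus, opossum and 15 eutherians spanning Perissodactyla,
Cetartiodactyla, Carnivora, Glires and Primates — because the analysis
depends only on clade-level patterns and the totals (30 species, 10
members). Presence follows the rule "present in every taxon from the
member's origin clade onward", with the documented exceptions: ApoC-I,
ApoC-II and ApoE absent in birds, ApoC-I additionally absent in
cetartiodactyls and platypus, ApoA-V absent in platypus, and ApoC-IA
present only in nonhuman primates. Running the reconstruction:

```{r fixture}
fx <- apo_fixture()
rep <- reconstruct_all(fx$tree, fx$matrix)
rep
emergence_order(fx$tree, fx$matrix)
```

Eight gains on the tree, two pre-root origins, seven losses. One
curation ambiguity deserves note: the literature contains both the
assignment of ApoA-II to Holostei with ApoE to Coelacanthiformes and the
swapped pairing. The fixture encodes the former. Because the ladder
places teleosts between the gar and the coelacanth, ApoC-I/ApoC-II then
emerge *between* ApoA-II and ApoE — any total order among those three is
sensitive to that choice, which is why the package reports per-member
origin nodes and treats the total order as derived, not as ground
truth.

## Homology assignment

The identification stage stands in for a BLASTP screen at desk scale:
exact Smith–Waterman local alignment of every candidate against the
query panel.

* **Scoring** defaults to BLOSUM62 with affine gap penalties of 11
  (opening) and 1 per gapped position — the standard protein-search
  default. A gap of length $L$ costs $11 + L$. The ambiguity residue X
  scores 0 against everything, so stretches of unknown sequence neither
  help nor hurt.
* **Normalization.** A candidate's raw score against its best query is
  divided by that query's self-alignment score, giving a length-free
  value in $[0, 1]$ (1 = identical to the query). The default acceptance
  threshold is 0.25; there is no canonical cutoff for normalized local
  alignment scores, so the value is documented and exposed as a parameter
  everywhere. At 0.25, shuffled-composition decoys score well below the
  cutoff while family members at 20% divergence score far above; both
  margins are exercised in the tests.
* **Ties** between queries are broken alphabetically by family name, so
  assignment is independent of panel order.
* **Redundancy filtering** (`dedupe`) removes, within each taxon, exact
  duplicates and "partials" — sequences whose best local alignment to a
  longer kept sequence of the same taxon covers ≥ 90% of their own length
  at ≥ 90% identity. Records are processed longest-first (ties by
  identifier) for determinism. Cross-taxon duplicates are kept: identical
  orthologs in two species are two data points.

A limitation worth stating: absence is declared when no candidate passes
the threshold in the supplied proteome. A genome-level six-frame search
confirming absence is out of scope, so unannotated genes read as absent.

## Distance phylogenies

The per-family tree stage implements the distance machinery:
complete deletion (every column containing `-`, `.`, `X` or `?` in any
row is dropped), p-distance or Poisson-corrected distance
$d = -\ln(1-p)$, Saitou–Nei neighbor joining (BioNJ variance weighting
behind a flag), and column bootstrap. Choices that matter:

* Taxa are sorted alphabetically before agglomeration so that ties in
  the Q-criterion resolve identically regardless of input order.
* Negative NJ branch-length estimates are clamped to 0.
* A pair differing at every position has no finite Poisson distance; the
  computation stops with a "saturated pair" error rather than guessing.
  Bootstrap replicates that saturate are skipped and support percentages
  are taken over the completed replicates.
* An alignment of identical sequences carries no signal; the bootstrap
  returns a zero-length star tree rather than erroring.
* Supports are percentages of replicates containing the same unrooted
  bipartition, written as internal node labels; `node_support()` reads
  them back.
* Trees over more than 64 taxa are refused: beyond that, a proper
  likelihood pipeline is the right tool, and this package does not
  pretend to be one. Maximum-likelihood search (JTT, NNI) is deliberately
  not implemented.

## The repeat-architecture event calculus

Apolipoprotein genes share one 33-codon block plus variable 22- and
11-codon amphipathic repeats, in a gene model of three introns/four exons
(two/three for ApoA-IV and ApoC-IV). An architecture is the multiset of
repeat units plus the intron/exon counts; `architecture_diff()` returns
the minimal event list (unit duplications/deletions per size, intron
gains/losses) transforming one into another. Unit *order* is ignored —
the documented evidence is counts, never positions — and the output
order (33, 22, 11, introns) is fixed for determinism.

The packaged architectures encode the documented scenario: the primordial
ApoA-I-like gene; ApoA-IV (first intron lost, three 22- and one 11-codon
duplication); ApoE (one 22 + one 11 from the ApoA-I lineage); ApoA-V
(one 11 from the ApoA-IV lineage); eleven 11-codon deletions on the path
to ApoA-II and the ApoC ancestor (ten or eleven are equally consistent
with the known gene models; eleven is encoded and the alternative noted
in the packaged file — nothing downstream depends on the choice); one
and two 22-codon
deletions yielding ApoC-II and ApoC-I; an 11-codon deletion and
duplication yielding ApoC-III and ApoC-IV. The ancestral repeat
composition is under-determined (only "similar to ApoA-I or ApoA-IV" is
known); it is anchored to the ApoA-I-like structure, and since every
assertion tested is a *difference* between architectures, the anchor
cancels out of all of them. Intron events are placed per the final
intron counts of each gene model only; the per-edge placement of intron
changes along the ApoC lineage is not otherwise determined.

## Synthetic data: what it emulates and what it does not

Three generators make the pipeline testable end to end without
downloads; all are pure functions of (configuration, seed).

* `simulate_characters()` runs the generative Dollo process: one gain
  per character (on a chosen or random branch), then absorbing loss with
  a fixed per-branch probability. Loss is per *branch*, not per unit
  length, because the fixture tree carries no meaningful branch lengths.
  With loss probability 0 the reconstruction must recover every gain
  branch exactly — and does, across all seeds tested; with losses the
  inferred gain is provably confined to the true gain clade and the
  inferred loss count bounded by the true count. Default loss
  probability in the tests is 0.2–0.3, high enough to exercise multi-loss
  scenarios on 10–12-leaf trees.
* `simulate_sequences()` evolves a root sequence site-independently:
  along a branch of length $t$ a site substitutes with probability
  $1-\mathrm{e}^{-t}$ to a uniformly drawn different residue. This
  single-jump uniform-exchange model is deliberately simple — no
  JTT/WAG exchangeabilities, no rate heterogeneity, no indels (complete
  deletion would remove them anyway). Passing bootstrap and NJ tests on
  this model shows the *machinery* is correct; it does not certify
  performance on real proteins, whose substitution process is rougher.
* `simulate_proteome()` emits, per taxon, each truly present family
  member as its query mutated at a fixed fraction of positions, plus
  composition-preserving shuffled decoys. `synthetic_panel()` supplies
  ten independent random queries at human-precursor-like lengths
  (83–396 residues). Real paralogs share ancestry and can cross-score;
  independent random queries cannot, so the recovery experiments bound
  the pipeline's behavior under clean separation, not under hard
  paralogy.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: 500 random
tree/character instances (4–12 leaves) against the exhaustive single-gain
oracle; 1000 simulated characters on a 12-leaf tree at loss 0 and 0.3;
40 random short pairs (lengths ≤ 8, reduced alphabet) against the
brute-force alignment enumeration; 100 additive matrices (4–15 leaves)
for NJ consistency; and 20 bootstrap runs of 100 replicates on 2000
simulated columns for a 6-leaf tree. These sizes give the properties
real statistical teeth while keeping a full run in the tens of seconds;
the bootstrap default in the package itself remains 1000 replicates.
Every stochastic step takes an explicit integer seed and restores the
caller's RNG state, so identical configurations reproduce byte-identical
outputs.

## Known limitations

* Absence calls inherit the annotation quality of the input proteomes.
* Multiple-gain (convergent origin) scenarios, probabilistic gain/loss
  rate models, and gene-tree/species-tree reconciliation are out of
  scope: the Dollo model is the explicit assumption.
* The aligner is exact Smith–Waterman; it has no E-value statistics and
  is not built for genome-scale screening.
* The emergence order is only as resolved as the species tree; on the
  coarse fixture ladder, equally deep origins are reported as
  simultaneous rather than force-ranked.
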