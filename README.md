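# apoevol

Gain and loss evolution of the vertebrate apolipoprotein family.

The exchangeable apolipoproteins (ApoA-I/II/IV/V, ApoC-I–IV and ApoE) are
lipid-transport proteins whose gene family expanded and contracted
repeatedly across vertebrate evolution: some members are ancient and
ubiquitous, others arose in specific clades and were later lost again in
particular lineages (birds, cetartiodactyls, platypus, even humans, where
the primate-specific ApoC-IA became a pseudogene). `apoevol` is an R
package for reconstructing that history from sequence data: it identifies
family members in candidate proteomes, scores their presence and absence
across species, maps gain and loss events onto a species tree, ranks
members by evolutionary emergence, builds distance phylogenies with
bootstrap support, and models the evolution of the family's
characteristic 33/22/11-codon repeat-block gene architecture. It is aimed
at molecular evolutionists studying gene-family dynamics on phyletic
patterns.

## The model

Presence/absence of each family member across taxa (its *phyletic
pattern*) is analysed under **Dollo parsimony**: a member is gained at
most once and may be lost any number of times. For a character with
possessing leaf set *P* on rooted species tree *T*, the most parsimonious
single-gain scenario is

- **gain** on the branch subtending `MRCA(P)` — or *before the root*
  (`PRE_ROOT`) when the member is present in every sampled species, in
  which case its origin is unobservable on *T*;
- one **loss** on each maximal subtree below the gain node that contains
  no possessing leaf.

The package proves (against an exhaustive oracle, in its test suite) that
this placement minimizes the loss count over all single-gain scenarios.
Members are ranked by the depth of their gain node to give the emergence
order. Homology assignment uses Smith–Waterman local alignment (BLOSUM62,
affine gaps 11/1) against a query panel, with scores normalized by the
query self-score; distance trees use p- or Poisson-corrected distances
(`d = −ln(1 − p)`) after complete deletion of gapped columns, Saitou–Nei
neighbor joining, and nonparametric bootstrap over alignment columns.

## Worked example

The packaged fixture encodes the curated presence/absence of the 10
family members across 30 representative vertebrates, with the ladder
species tree they were scored on:

```r
library(apoevol)

fx <- apo_fixture()
fx$matrix
#> phyletic_matrix: 30 taxa x 10 characters
#>   present: 220  absent: 80  unknown: 0

rep <- reconstruct_all(fx$tree, fx$matrix)
rep
#> event_report: 10 characters; 8 gain events (10 origins incl. pre-root); 7 loss events
```

Eight members were gained on the tree (ApoA-I and ApoA-IV predate the
root — they are present in all 30 species, so their origin is older than
the sampled taxa), and seven losses are required. Where are the losses?

```r
ev <- events_by_branch(rep)
ev[ev$event == "loss", c("branch", "count", "characters")]
#>                    branch count          characters
#>  Ornithorhynchus_anatinus     2       ApoA-V,ApoC-I
#>              Homo_sapiens     1             ApoC-IA
#>                      Aves     3 ApoC-I,ApoC-II,ApoE
#>           Cetartiodactyla     1              ApoC-I
```

Three members vanished on the bird stem; ApoC-I was additionally lost in
cetartiodactyls and platypus (along with ApoA-V there); and ApoC-IA,
present only in nonhuman primates, was lost on the human branch. The
emergence ranking orders members from pre-root to youngest:

```r
emergence_order(fx$tree, fx$matrix)
#>   rank depth        members
#> 1    1    -1 ApoA-I,ApoA-IV
#> 2    2     1        ApoA-II
#> 3    3     2 ApoC-I,ApoC-II
#> 4    4     3           ApoE
#> 5    5     4         ApoA-V
#> 6    6     5       ApoC-III
#> 7    7     8        ApoC-IV
#> 8    8    10        ApoC-IA
```

Depth is the number of tree edges from the root to the gain node (−1 =
before the root). A command-line interface wrapping the same functions is
installed at `system.file("cli", "apoevol.R", package = "apoevol")`, with
subcommands `identify`, `matrix`, `events`, `order`, `phylo`,
`arch-diff`, `simulate` and `run`.

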