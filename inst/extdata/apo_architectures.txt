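# Apolipoprotein gene repeat-block architectures.
# units: mature-peptide repeat blocks in codons (one 33-codon common block
# plus 22- and 11-codon amphipathic repeats); unit order is not meaningful
# (the event calculus uses multisets).
# The ApoA-II/ApoC branch is encoded with eleven 11-codon deletions from the
# ApoA-IV-like gene; the alternative of ten deletions (one more retained
# 11-codon unit in ApoA-II, ApoC-ancestral and their descendants) is
# equally consistent with the known gene models.
# ApoC-IA is the primate acidic duplicate of ApoC-I and shares its
# architecture.

name: Ancestral
introns: 3
exons: 4
units: 33,22,22,22,11,11,11,11,11,11,11,11,11,11,11,11

name: ApoA-I
introns: 3
exons: 4
units: 33,22,22,22,11,11,11,11,11,11,11,11,11,11,11,11

name: ApoE
introns: 3
exons: 4
units: 33,22,22,22,22,11,11,11,11,11,11,11,11,11,11,11,11,11

name: ApoA-IV
introns: 2
exons: 3
units: 33,22,22,22,22,22,22,11,11,11,11,11,11,11,11,11,11,11,11,11

name: ApoA-V
introns: 3
exons: 4
units: 33,22,22,22,22,22,22,11,11,11,11,11,11,11,11,11,11,11,11,11,11

name: ApoA-II
introns: 3
exons: 4
units: 33,22,22,22,22,22,22,11,11

name: ApoC-ancestral
introns: 3
exons: 4
units: 33,22,22,22,22,22,22,11,11

name: ApoC-I
introns: 3
exons: 4
units: 33,22,22,22,22,11,11,11

name: ApoC-IA
introns: 3
exons: 4
units: 33,22,22,22,22,11,11,11

name: ApoC-II
introns: 3
exons: 4
units: 33,22,22,22,22,22,11,11,11

name: ApoC-III
introns: 3
exons: 4
units: 33,22,22,22,22,22,22,11

name: ApoC-IV
introns: 2
exons: 3
units: 33,22,22,22,22,22,22,11,11,11
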