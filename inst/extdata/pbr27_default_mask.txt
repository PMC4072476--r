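# Default 27-codon peptide-binding-region (PBR) mask for DRB1.
# Positions are 1-based codons of the mature beta-1 domain (apply a
# signal-peptide offset to address complete CDS; DRB1 leaders are 29
# codons).
#
# This file is an editable default: 24 commonly cited DR beta-chain
# peptide-contact residues plus the three additional groove residues
# 57, 67 and 90. Replace it with your preferred contact-residue
# definition if needed; every analysis accepts an arbitrary mask.
9
11
13
26
28
30
32
37
38
47
56
57
60
61
65
67
68
70
71
74
78
81
82
85
86
89
90
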