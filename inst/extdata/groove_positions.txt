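# Binding-groove residue positions used to build HLA class II
# pseudo-sequences (15 alpha-chain + 19 beta-chain residues).
# Positions are 1-based indices into the mature chain sequences and
# follow the NetMHCIIpan-3.0 residue selection (Karosiene et al.,
# Immunogenetics 2013). This file is data, not code: edit it to use a
# different groove definition, and remember that every
# pseudo-sequence-derived result is conditional on this table.
# line 1: alpha chain (15 positions); line 2: beta chain (19 positions)
9 11 22 24 31 52 53 58 59 61 65 66 68 72 73
9 11 13 26 28 30 47 57 67 70 71 74 77 78 81 85 86 89 90
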