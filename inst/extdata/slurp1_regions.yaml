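# Cys-anchored region scheme for SLURP-1 (author numbering, Met0 = 0).
# Package-chosen boundaries derived from the invariant disulfide pattern
# (Cys3-Cys28, Cys21-Cys51, Cys55-Cys71, Cys72-Cys77) and the extra loop-I
# disulfide Cys6-Cys15: the loops run between the anchoring Cys positions,
# the head is everything else except the first residue.  Aggregates must
# echo the scheme that produced them; edit here to explore sensitivity.
residues: 0-81
exclude: [0, 1]
loop_i: 4-20
loop_ii: 29-50
loop_iii: 56-70
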