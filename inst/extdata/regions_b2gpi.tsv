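# Region/motif definitions for beta-2 glycoprotein I, residue numbering
# includes the 19-residue signal peptide (the Domain V tryptophan of aPL
# loop 2 is residue 335 here; it is 316 when the signal peptide is dropped).
# Domain V loops: phospholipid-binding (aPL) loops and the anti-A1 loop.
# Domain I-II entries are epitope motifs; motif_5 stands in for the segment
# that includes the DI-DII linker peptide (exact span not fixed in the
# literature) and, like every row here, can be overridden by a user config.
name	domain_tag	residues
aPL_loop_1	DV	303,305,306
aPL_loop_2	DV	332,334,335
anti_A1_loop	DV	301,327,336
K269_K270	DV	269,270
motif_1	DI	29-36
motif_2	DI	35-43
motif_3	DI	58-62
motif_4	DI	69-77
motif_5	DI-II	84-91
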