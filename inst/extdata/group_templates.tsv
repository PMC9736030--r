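# bzipscan basic+hinge signature templates, v1
# 30 columns; '*' matches anything; '[XY]' = one column matching X or Y.
# Column 12 is the invariant Asn anchor and column 20 the R/K anchor of the
# N-x7-R/K motif; fixed letters at those columns that contradict the anchor
# (group A's K, group J's I) are tolerated against the canonical residue but
# do not count toward matched_positions. tie_priority: 1 wins ties.
group	tie_priority	template	binding_site
A	4	*********MIK************QAY***	ABREs with the core ACGT or others containing GCGT/AAGT
B	2	**********RNRESAQLSR**********	G- and C-boxes with equal affinity
C	6	***********************QAHLEE*	Hybrid ACGT elements such as G/C, G/A, and C/G boxes
D	1	********LAQN**AA*KSR***KAYVQQ*	C-box sequence
E	7	*********A**************QYI[SA]E*	Unknown
F/K	10	**************A***************	C-box elements
G/M/S	5	***********N**SA**SR**********	G-box and/or G-box-like sequences
H	3	***********NRVSAQQAR**********	G-box-like sequences
I	8	*******************K**********	Sequences other than those containing a palindromic ACGT core, such as CCA/TGG repeats
J	9	*******************I**********	Unknown
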