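# Curated functional-center search motifs (PROSITE dialect, 1-based inclusive match coordinates)
# registry_version: 1
motif_id	center_class	pattern	expected_min_len	expected_max_len	notes
GC	GC	[KS]x[CGS]x(10)[KR]	14	14	guanylate cyclase catalytic center; 14-aa consensus
AC	AC	[RKS]x[DE]x(10)[KR]	14	14	adenylate cyclase catalytic center; 14-aa consensus
PDE	PDE	[YFW]Hx[YFW]Rx(20,40)[HRK][DE]	27	47	cyclic nucleotide phosphodiesterase catalytic center
HNOX	HNOX	Hx(12)Px(14,16)YxSxR	33	35	heme-nitric oxide/oxygen (H-NOX) gas-sensing center; H is the distal NO ligand, YxSxR stabilizes the porphyrin ring
ABA	ABA	[DE]x(7,8)Rx(3,4)[DE]x(5)Yx(6)H	26	28	abscisic-acid-interacting center derived from PYR/PYL receptor binding residues
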