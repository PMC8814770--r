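# Dissociation constants (pKa) used by the isoelectric-point calculator.
# Simplified Bjellqvist set: one pKa per ionizable group, no positional
# adjustment of internal residues and a single N-terminal value for all
# residues. Bjellqvist et al. (1993) Electrophoresis 14:1023-1031.
# type: pos = group is positively charged below its pKa,
#       neg = group is negatively charged above its pKa.
group	type	pka
Nterm	pos	7.50
K	pos	10.00
R	pos	12.00
H	pos	5.98
Cterm	neg	3.55
D	neg	4.05
E	neg	4.45
C	neg	9.00
Y	neg	10.00
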