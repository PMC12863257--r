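# RNA nearest-neighbor duplex free-energy parameters, 37 C, kcal/mol.
# Watson-Crick stack values from the Xia et al. thermodynamic set;
# G:U wobble stacks and loop penalties from the Turner 2004 compilation.
# stack <top> <bot> <dG>: helix 5'-top-3' over 3'-bot-5' (top[k] pairs bot[k]).
# bulge/internal <len> <penalty>: destabilization by unpaired-loop length.
init	4.09
terminal_au	0.45
stack	AA	UU	-0.93
stack	AU	UA	-1.10
stack	AC	UG	-2.24
stack	AG	UC	-2.08
stack	AG	UU	-0.60
stack	AU	UG	-1.40
stack	UA	AU	-1.33
stack	UU	AA	-0.93
stack	UC	AG	-2.35
stack	UG	AC	-2.11
stack	UG	AU	-1.00
stack	UU	AG	-1.30
stack	CA	GU	-2.11
stack	CU	GA	-2.08
stack	CC	GG	-3.26
stack	CG	GC	-2.36
stack	CG	GU	-1.40
stack	CU	GG	-2.10
stack	GA	CU	-2.35
stack	GU	CA	-2.24
stack	GC	CG	-3.42
stack	GG	CC	-3.26
stack	GG	CU	-1.50
stack	GU	CG	-2.50
stack	GA	UU	-1.30
stack	GU	UA	-1.40
stack	GC	UG	-2.50
stack	GG	UC	-2.10
stack	GG	UU	-0.50
stack	GU	UG	1.30
stack	UA	GU	-1.00
stack	UU	GA	-0.60
stack	UC	GG	-1.50
stack	UG	GC	-1.40
stack	UG	GU	0.30
stack	UU	GG	-0.50
bulge	1	3.80
bulge	2	2.80
bulge	3	3.20
bulge	4	3.60
bulge	5	4.00
bulge	6	4.40
bulge	7	4.60
bulge	8	4.70
bulge	9	4.80
bulge	10	4.90
bulge	11	5.00
bulge	12	5.10
bulge	13	5.20
bulge	14	5.30
bulge	15	5.40
bulge	16	5.40
bulge	17	5.50
bulge	18	5.50
bulge	19	5.60
bulge	20	5.70
bulge	21	5.70
bulge	22	5.80
bulge	23	5.80
bulge	24	5.80
bulge	25	5.90
bulge	26	5.90
bulge	27	6.00
bulge	28	6.00
bulge	29	6.00
bulge	30	6.10
internal	1	Inf
internal	2	1.00
internal	3	1.00
internal	4	1.10
internal	5	2.00
internal	6	2.00
internal	7	2.10
internal	8	2.30
internal	9	2.40
internal	10	2.50
internal	11	2.60
internal	12	2.70
internal	13	2.80
internal	14	2.90
internal	15	2.90
internal	16	3.00
internal	17	3.10
internal	18	3.10
internal	19	3.20
internal	20	3.30
internal	21	3.30
internal	22	3.40
internal	23	3.40
internal	24	3.50
internal	25	3.50
internal	26	3.50
internal	27	3.60
internal	28	3.60
internal	29	3.70
internal	30	3.70
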