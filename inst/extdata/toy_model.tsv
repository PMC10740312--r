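#objective BIOMASS
#formula glc_e=C6H12O6
#formula X=R
reaction	equation	lower	upper	gpr	subsystem
EX_glc	glc_e ->	-1000	1000		Exchange
P_A1	glc_e -> M_A1	    0	1000	g_A1	Pathway A
P_A2	M_A1 <=> X	-1000	1000	g_A2	Pathway A
P_B1	glc_e -> M_B1	    0	1000	g_B1	Pathway B
P_B2	M_B1 -> X	    0	1000	g_B2	Pathway B
BIOMASS	X ->	    0	1000	g_bio	Biomass
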