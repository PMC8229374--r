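# fluxprint model	warburg_toy
reaction_id	lower_bound	upper_bound	gpr	subsystem	objective	stoichiometry
EX_glc_e	-10	200		exchange/demand	0	glc_e:-1
GLCt	0	200	g0001 or g0002	transport, extracellular	0	glc_e:-1;glc_c:1
HEX1	0	200	g0003 and (g0004 or g0005)	glycolysis	0	glc_c:-1;atp_c:-1;g6p_c:1;adp_c:1
GAPD	0	200	g0006 and g0007	glycolysis	0	atp_c:3;g6p_c:-1;adp_c:-3;nad_c:-2;pyr_c:2;nadh_c:2
LDH_L	0	200	g0008 or g0009	glycolysis	0	nad_c:1;pyr_c:-1;nadh_c:-1;lac_c:1
D_LACt2	-200	200	g0010	transport, extracellular	0	lac_c:1;lac_e:-1
EX_lac_e	0	200		exchange/demand	0	lac_e:-1
PDHm	0	200	g0011 and g0012	citric acid cycle	0	nad_c:-1;pyr_c:-1;nadh_c:1;accoa_c:1
CSm	0	200	g0013 and (g0014 or g0015)	citric acid cycle	0	atp_c:1;adp_c:-1;nad_c:-3;nadh_c:3;accoa_c:-1
ATPS4mi	0	200	g0016 and g0017	oxidative phosphorylation	0	atp_c:5;adp_c:-5;nad_c:2;nadh_c:-2;o2_c:-1
O2t	-200	200	g0018	transport, extracellular	0	o2_c:1;o2_e:-1
EX_o2_e	-5	200		exchange/demand	0	o2_e:-1
DM_atp_c_	1	200		exchange/demand	0	atp_c:-1;adp_c:1
biomass_reaction	0	200		biomass	1	atp_c:-20.00000000000000000;g6p_c:-0.20000000000000001;adp_c:20.00000000000000000;pyr_c:-0.29999999999999999;accoa_c:-0.29999999999999999;bm_c:1.00000000000000000
EX_biomass	0	200		exchange/demand	0	bm_c:-1
EX_sub1_e	-4	200		pentose phosphate pathway	0	sub1_e:-1
SUB1t	0	200	g0019	pentose phosphate pathway	0	sub1_e:-1;sub1_c:1
P1R1	0	200	g0020 and g0021	pentose phosphate pathway	0	sub1_c:-1;int1_1_c:1
P1R2	0	200	g0022	pentose phosphate pathway	0	int1_1_c:-1;int1_2_c:1
P1R3	0	200	g0023 or g0024	pentose phosphate pathway	0	atp_c:2;adp_c:-2;nad_c:-1;pyr_c:1;nadh_c:1;int1_2_c:-1
EX_sub2_e	-5	200		fatty acid synthesis	0	sub2_e:-1
SUB2t	0	200	g0025	fatty acid synthesis	0	sub2_e:-1;sub2_c:1
P2R1	0	200	g0026 and g0027	fatty acid synthesis	0	sub2_c:-1;int2_1_c:1
P2R2	0	200	g0028 or g0029	fatty acid synthesis	0	atp_c:3;adp_c:-3;nad_c:-1;pyr_c:1;nadh_c:1;int2_1_c:-1
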