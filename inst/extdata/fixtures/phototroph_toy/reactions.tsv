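id	name	stoichiometry	lb	ub	objective_coefficient	gene_associated	subsystem
EX_photon_e	Photon exchange	photon_e:-1	-45	0	0	FALSE	Exchange
PHOt	Photon capture	photon_e:-1;photon_c:1	0	1000	0	TRUE	Photosynthesis
LEF	Linear electron flow	photon_c:-1;adp_c:-1.28;pi_c:-1.28;nadp_c:-1;atp_c:1.28;nadph_c:1	0	1000	0	TRUE	Photosynthesis
CEF	Cyclic electron flow	photon_c:-1;adp_c:-1;pi_c:-1;atp_c:1	0	1000	0	TRUE	Photosynthesis
EX_co2_e	CO2 exchange	co2_e:-1	-100	1000	0	FALSE	Exchange
CO2t	CO2 transport	co2_e:-1;co2_c:1	-1000	1000	0	TRUE	Transport
CBB	Carbon fixation	co2_c:-1;atp_c:-3;nadph_c:-2;h2o_c:-1;cx_c:1;adp_c:3;pi_c:3;nadp_c:2	0	1000	0	TRUE	Calvin-Benson-Bassham cycle
BIOMASS	Biomass drain	cx_c:-1;atp_c:-1.5;nadph_c:-0.5;adp_c:1.5;pi_c:1.5;nadp_c:0.5	0	1000	1	FALSE	Biomass
PROD	Alkene synthesis	cx_c:-2;atp_c:-2;nadph_c:-2;prod_c:1;adp_c:2;pi_c:2;nadp_c:2;h2o_c:2	0	1000	0	TRUE	Heterologous pathway
PRODt	Alkene export transport	prod_c:-1;prod_e:1	0	1000	0	TRUE	Transport
EX_prod_e	Alkene exchange	prod_e:-1	0	1000	0	FALSE	Exchange
ATPM	ATP maintenance	atp_c:-1;h2o_c:-1;adp_c:1;pi_c:1;h_c:1	0	1000	0	FALSE	Maintenance
CAT	Catabolic oxidation	cx_c:-1;nad_c:-2;h2o_c:-1;co2_c:1;nadh_c:2;h_c:2	0	1000	0	TRUE	Catabolism
THD	Transhydrogenase	nadh_c:-1;nadp_c:-1;nad_c:1;nadph_c:1	0	1000	0	TRUE	Redox balancing
EX_h2o_e	Water exchange	h2o_e:-1	-1000	1000	0	FALSE	Exchange
H2Ot	Water transport	h2o_e:-1;h2o_c:1	-1000	1000	0	TRUE	Transport
EX_h_e	Proton exchange	h_e:-1	-1000	1000	0	FALSE	Exchange
Ht	Proton transport	h_e:-1;h_c:1	-1000	1000	0	TRUE	Transport
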