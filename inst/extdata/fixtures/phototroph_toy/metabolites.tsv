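id	name	compartment	formula	charge
photon_e	Photon (extracellular)	e		0
photon_c	Photon (cytoplasm)	c		0
co2_e	Carbon dioxide (extracellular)	e	CO2	0
co2_c	Carbon dioxide	c	CO2	0
h2o_e	Water (extracellular)	e	H2O	0
h2o_c	Water	c	H2O	0
h_e	Proton (extracellular)	e	H	0
h_c	Proton	c	H	0
pi_c	Orthophosphate	c		0
atp_c	ATP	c		0
adp_c	ADP	c		0
nadp_c	NADP+	c		0
nadph_c	NADPH	c		0
nad_c	NAD+	c		0
nadh_c	NADH	c		0
cx_c	Fixed carbon unit	c	CH2O	0
prod_c	Alkene product	c	C2H4	0
prod_e	Alkene product (extracellular)	e	C2H4	0
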