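# 1-undecene route: UndA-type oxidative decarbonylation of dodecanoate
# (lauric acid) from fatty acid biosynthesis.
# SYNTHETIC TRANSCRIPTION (see curation config header).
name: undecene
metabolites:
  - {id: undec_c, name: 1-undecene, compartment: c, formula: C11H22, charge: 0}
additions:
  - {id: UNDA, name: UndA fatty acid decarboxylase-desaturase, stoichiometry: "ddca_c:-1;o2_c:-1;h_c:-2;undec_c:1;co2_c:1;h2o_c:2", lb: 0, ub: 1000, gene_associated: true, subsystem: Heterologous 1-undecene pathway}
  - {id: EX_undec_c, name: 1-undecene export, stoichiometry: "undec_c:-1", lb: 0, ub: 1000, gene_associated: false, subsystem: Heterologous 1-undecene pathway}
export_reaction_id: EX_undec_c
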