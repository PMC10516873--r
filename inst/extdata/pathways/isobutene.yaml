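# Isobutene route: oxidative decarboxylation of 3-methyl-2-oxobutanoate
# (ketoisovalerate) from branched-chain amino acid biosynthesis.
# SYNTHETIC TRANSCRIPTION (see curation config header).
name: isobutene
metabolites:
  - {id: ibene_c, name: Isobutene, compartment: c, formula: C4H8, charge: 0}
additions:
  - {id: KIVD_IB, name: Ketoisovalerate oxidative decarboxylase, stoichiometry: "3mob_c:-1;o2_c:-0.5;h_c:-2;ibene_c:1;co2_c:2;h2o_c:1", lb: 0, ub: 1000, gene_associated: true, subsystem: Heterologous isobutene pathway}
  - {id: EX_ibene_c, name: Isobutene export, stoichiometry: "ibene_c:-1", lb: 0, ub: 1000, gene_associated: false, subsystem: Heterologous isobutene pathway}
export_reaction_id: EX_ibene_c
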