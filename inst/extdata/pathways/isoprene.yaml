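# Isoprene route: isoprene synthase acting on DMAPP, plus cytoplasmic
# export drain. SYNTHETIC TRANSCRIPTION (see curation config header).
name: isoprene
metabolites:
  - {id: iprene_c, name: Isoprene, compartment: c, formula: C5H8, charge: 0}
additions:
  - {id: ISPS, name: Isoprene synthase, stoichiometry: "dmpp_c:-1;iprene_c:1;ppi_c:1", lb: 0, ub: 1000, gene_associated: true, subsystem: Heterologous isoprene pathway}
  - {id: EX_iprene_c, name: Isoprene export, stoichiometry: "iprene_c:-1", lb: 0, ub: 1000, gene_associated: false, subsystem: Heterologous isoprene pathway}
export_reaction_id: EX_iprene_c
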