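# Ethylene route: ethylene-forming enzyme (EFE) on 2-oxoglutarate; the
# canonical stoichiometry releases three CO2 per ethylene, which is why
# ethylene shows the highest carbon loss of the four alkenes.
# SYNTHETIC TRANSCRIPTION (see curation config header).
name: ethylene
metabolites:
  - {id: eth_c, name: Ethylene, compartment: c, formula: C2H4, charge: 0}
additions:
  - {id: EFE, name: Ethylene-forming enzyme, stoichiometry: "akg_c:-1;o2_c:-1;eth_c:1;co2_c:3;h2o_c:1", lb: 0, ub: 1000, gene_associated: true, subsystem: Heterologous ethylene pathway}
  - {id: EX_eth_c, name: Ethylene export, stoichiometry: "eth_c:-1", lb: 0, ub: 1000, gene_associated: false, subsystem: Heterologous ethylene pathway}
export_reaction_id: EX_eth_c
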