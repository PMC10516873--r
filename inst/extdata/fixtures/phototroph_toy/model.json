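{"model_id":"phototroph_toy","biomass_ids":{"autotrophic":"BIOMASS"},"product_export":"EX_prod_e","note":"synthetic fixture with hand-derived closed-form optima"}
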