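label: forward_risk_grid
type: risk_table
network:
  priors:
    leak:
      mean: "1%"
      nu: 9.0
    link_ng:
      mean: "10%"
      nu: 9.0
    link_g:
      mean: "90%"
      nu: 9.0
expected:
  provenance: derived
  parameterization: beta_nu9
  note: "forward risk over the active-cause grid; checked as an ordering property"
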