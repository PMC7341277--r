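label: prior_group_4
type: risk_table
network:
  priors:
    leak:
      mean: "1%"
      nu: 9.0
    link_ng:
      mean: "30%"
      nu: 9.0
    link_g:
      mean: "50%"
      nu: 9.0
expected:
  provenance: paper
  parameterization: beta_nu9
  note: "ordering property only; the printed cell values rest on unpublished draw counts and Beta shapes"
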