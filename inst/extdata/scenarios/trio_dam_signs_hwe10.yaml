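label: trio_dam_signs_hwe10
type: query
network:
  genetic_model: recessive
  priors:
    leak: 0.0
    link_ng: 0.1
    link_g: 1.0
  founders:
    sire: hwe(0.1)
    dam: uniform
query: G_offsp
evidence:
  P_dam: "T"
  D_dam: "F"
  E_dam: "F"
  A_dam: "F"
expected:
  provenance: paper
  parameterization: deterministic_limit
  tolerance: 0.005
  values:
    BB: 10.0
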