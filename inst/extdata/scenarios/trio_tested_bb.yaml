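label: trio_tested_bb
type: query
network:
  genetic_model: recessive
  priors:
    leak: 0.01
    link_ng: 0.1
    link_g: 0.9
  founders:
    sire: uniform
    dam: uniform
query: G_sire
evidence:
  G_offsp: BB
expected:
  provenance: paper
  parameterization: stated_means
  tolerance: 0.05
  values:
    AA: 0.0
    AB: 33.3
    BB: 66.7
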