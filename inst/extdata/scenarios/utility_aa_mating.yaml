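label: utility_aa_mating
type: utility
network:
  genetic_model: recessive
  priors:
    leak: 0.0
    link_ng: 0.1
    link_g: 1.0
  founders:
    sire: uniform
    dam: uniform
evidence:
  G_sire: AA
  G_dam: AA
utilities:
  AA: 100.0
  AB: 100.0
  BB: 0.0
expected:
  provenance: paper
  parameterization: deterministic_limit
  tolerance: 0.005
  value: 100.0
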