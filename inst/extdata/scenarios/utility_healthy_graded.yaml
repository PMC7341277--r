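label: utility_healthy_graded
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
  P_sire: "F"
  P_dam: "F"
  D_sire: "F"
  E_sire: "F"
  A_sire: "F"
  D_dam: "F"
  E_dam: "F"
  A_dam: "F"
utilities:
  AA: 100.0
  AB: 50.0
  BB: 0.0
expected:
  provenance: derived
  parameterization: deterministic_limit
  tolerance: 0.005
  value: 75.0
  note: "closed form 56.25 + 0.5 * 37.5; the externally quoted 74.88 is not reproduced (see documented discrepancies)"
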