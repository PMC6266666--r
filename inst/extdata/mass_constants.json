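{
  "delta_disulfide_per_bond": -2.01566,
  "delta_pyroglu": -17.02655,
  "delta_hydroxyethyl_per_cys": 44.02621,
  "delta_reduction_per_cys": 1.00783
}
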