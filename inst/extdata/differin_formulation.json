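{
  "name": "Differin",
  "drug_mass_fraction": 0.001,
  "applied_mass": 500,
  "density_discrete": 1.3,
  "density_continuous": 1.0,
  "fraction_discrete": 0.01,
  "Kp_dp_cp": 8.5e-06,
  "P_dp_cp": 2.9e-06,
  "A_dp_cp": 1,
  "release_lag": 0
}
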