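{
  "receptor_volume": 5.1,
  "orifice_area": 0.69,
  "membrane_thickness": 0.0025,
  "membrane_porosity": 0.7,
  "membrane_permeability": 0.5,
  "membrane_partition": 1,
  "sample_volume": 0.5,
  "sampling_times": [0.5, 1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 20, 24]
}
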