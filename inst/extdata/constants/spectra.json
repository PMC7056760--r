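{
  "version": "1.0",
  "Ho166": {
    "lines": {
      "energy_keV": [80.57, 1379.4, 1581.9, 1662.4],
      "photons_per_decay": [0.0671, 0.00922, 0.00187, 0.0012]
    },
    "continuum": {
      "edges_keV": [60, 88, 106, 129, 154, 226, 462, 992, 2000],
      "photons_per_decay": [0.005, 0.003, 0.0033, 0.003, 0.006, 0.008, 0.006, 0.002]
    }
  },
  "Tc99m": {
    "lines": {
      "energy_keV": 140.5,
      "photons_per_decay": 0.885
    },
    "continuum": {}
  }
}
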