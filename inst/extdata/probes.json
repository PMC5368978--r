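[
  {
    "name": "P-GSH",
    "analyte": "glutathione",
    "tau_unreacted": 6.0,
    "tau_reacted": 225.0,
    "linear_limit": 10.0,
    "saturation_conc": 20.0
  },
  {
    "name": "P-HP",
    "analyte": "hydrogen peroxide",
    "tau_unreacted": 5.5,
    "tau_reacted": 146.0,
    "linear_limit": 50.0,
    "saturation_conc": 100.0
  },
  {
    "name": "P-HA",
    "analyte": "hypochlorous acid",
    "tau_unreacted": 4.3,
    "tau_reacted": 90.5,
    "linear_limit": 40.0,
    "saturation_conc": 80.0
  }
]
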