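{
  "comment": "Text-printed kinetic constants for the exported alarmone synthetase; units in key names.",
  "km_donor_uM": 82,
  "vmax_pppGpp_uM_min": 110,
  "acceptors_km_uM": { "ATP": 1400 },
  "acceptors_vmax_uM_min": { "ATP": 114 },
  "enzyme_nM": 0.30,
  "reference_rate_uM_min": 23,
  "reference_atp_uM": 5000,
  "epsilon_per_mM": 3.88
}
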