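[
  {
    "event": 1,
    "fragment_id": "B",
    "dwell_start": 6,
    "dwell_end": 20,
    "gap": 2,
    "site_residues": "12,13,14,15"
  }
]
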