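{
  "name": "synthetic triprotic ampholyte",
  "sites": [
    {
      "label": "COOH",
      "kind": "acid",
      "charge_protonated": 0
    },
    {
      "label": "N14",
      "kind": "base",
      "charge_protonated": 1
    },
    {
      "label": "N18",
      "kind": "base",
      "charge_protonated": 1
    }
  ],
  "energies": {
    "111": 0,
    "011": 2,
    "101": 2.6,
    "110": 7.2,
    "001": 5.6,
    "010": 9.6,
    "100": 10.4,
    "000": 13.8
  }
}
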