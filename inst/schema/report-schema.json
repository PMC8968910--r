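{
  "title": "magnegel experiment report",
  "required": {
    "seed": "number",
    "versions": {
      "required": {
        "magnegel": "string",
        "r": "string"
      }
    },
    "device": {
      "required": {
        "midpoint_B_mT": "number",
        "mean_gradient_T_per_m": "number"
      }
    },
    "groups": "list"
  }
}
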