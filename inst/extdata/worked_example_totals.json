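{
  "denominator_policy": "declared_total",
  "declared_totals": {
    "int_munin2": 10000,
    "rpn_CRZ_1": 5000,
    "rpn_CRZ_2": 5000
  }
}
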