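{
  "name": "liver_disorders",
  "header": false,
  "separator": ",",
  "positive_class": "2",
  "comment": "UCI BUPA liver disorders dialect: headerless CSV, six blood-test / drinks attributes followed by the selector class column (1/2).",
  "columns": [
    {"name": "mcv", "kind": "continuous", "range": [65, 103]},
    {"name": "alkphos", "kind": "continuous", "range": [23, 138]},
    {"name": "sgpt", "kind": "continuous", "range": [4, 155]},
    {"name": "sgot", "kind": "continuous", "range": [5, 82]},
    {"name": "gammagt", "kind": "continuous", "range": [5, 297]},
    {"name": "drinks", "kind": "continuous", "range": [0, 20]},
    {"name": "selector", "kind": "label"}
  ]
}
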