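{
  "name": "hepatitis",
  "header": false,
  "separator": ",",
  "positive_class": "1",
  "comment": "UCI hepatitis dialect: headerless CSV, class column first (1 = die, 2 = live), binary attributes coded 1 = no, 2 = yes (sex: 1 = male, 2 = female), '?' marks missing cells. Documented ranges follow the dataset description.",
  "columns": [
    {"name": "class", "kind": "label"},
    {"name": "age", "kind": "continuous", "range": [7, 78]},
    {"name": "sex", "kind": "binary", "levels": ["1", "2"]},
    {"name": "steroid", "kind": "binary", "levels": ["1", "2"]},
    {"name": "antivirals", "kind": "binary", "levels": ["1", "2"]},
    {"name": "fatigue", "kind": "binary", "levels": ["1", "2"]},
    {"name": "malaise", "kind": "binary", "levels": ["1", "2"]},
    {"name": "anorexia", "kind": "binary", "levels": ["1", "2"]},
    {"name": "liver_big", "kind": "binary", "levels": ["1", "2"]},
    {"name": "liver_firm", "kind": "binary", "levels": ["1", "2"]},
    {"name": "spleen_palpable", "kind": "binary", "levels": ["1", "2"]},
    {"name": "spiders", "kind": "binary", "levels": ["1", "2"]},
    {"name": "ascites", "kind": "binary", "levels": ["1", "2"]},
    {"name": "varices", "kind": "binary", "levels": ["1", "2"]},
    {"name": "bilirubin", "kind": "continuous", "range": [0.3, 8]},
    {"name": "alk_phosphate", "kind": "continuous", "range": [26, 295]},
    {"name": "sgot", "kind": "continuous", "range": [14, 648]},
    {"name": "albumin", "kind": "continuous", "range": [2.1, 6.4]},
    {"name": "protime", "kind": "continuous", "range": [0, 100]},
    {"name": "histology", "kind": "binary", "levels": ["1", "2"]}
  ]
}
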