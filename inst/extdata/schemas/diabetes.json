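{
  "name": "diabetes",
  "header": false,
  "separator": ",",
  "positive_class": "1",
  "comment": "Pima Indians diabetes dialect: headerless CSV, eight clinical attributes followed by the binary outcome (1 = positive test, 0 = negative).",
  "columns": [
    {"name": "pregnancies", "kind": "continuous", "range": [0, 17]},
    {"name": "glucose", "kind": "continuous", "range": [0, 199]},
    {"name": "blood_pressure", "kind": "continuous", "range": [0, 122]},
    {"name": "skin_thickness", "kind": "continuous", "range": [0, 99]},
    {"name": "insulin", "kind": "continuous", "range": [0, 846]},
    {"name": "bmi", "kind": "continuous", "range": [0, 67.1]},
    {"name": "pedigree", "kind": "continuous", "range": [0.078, 2.42]},
    {"name": "age", "kind": "continuous", "range": [21, 81]},
    {"name": "outcome", "kind": "label"}
  ]
}
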