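{
  "name": "cha2ds2vasc",
  "components": [
    {"name": "congestive_heart_failure", "type": "diagnosis", "points": 1,
     "code_set": {"codes": ["I50", "DX_HEART_FAILURE"], "match_mode": "prefix"}},
    {"name": "hypertension", "type": "diagnosis", "points": 1,
     "code_set": {"codes": ["I10", "I11", "I12", "I13", "I15", "DX_HYPERTENSION"], "match_mode": "prefix"}},
    {"name": "age_75_plus", "type": "age_at_least", "points": 2, "value": 75},
    {"name": "diabetes", "type": "diagnosis", "points": 1,
     "code_set": {"codes": ["E10", "E11", "E13", "E14", "DX_DIABETES"], "match_mode": "prefix"}},
    {"name": "prior_stroke_tia", "type": "diagnosis", "points": 2,
     "code_set": {"codes": ["I63", "I64", "G45"], "match_mode": "prefix"}},
    {"name": "vascular_disease", "type": "diagnosis", "points": 1,
     "code_set": {"codes": ["I21", "I25", "I70", "I73"], "match_mode": "prefix"}},
    {"name": "age_65_74", "type": "age_between", "points": 1, "min": 65, "max": 74},
    {"name": "female_sex", "type": "sex", "points": 1, "value": "female"}
  ]
}
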