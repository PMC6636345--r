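{
  "study_window": ["2010-01-01", "2015-12-31"],
  "washout_days": 365,
  "lookback_days": 365,
  "max_followup_days": 730,
  "gap_days": 30,
  "caliper": 0.2,
  "caliper_scale": "logit_sd",
  "smd_threshold": 0.1,
  "alpha": 0.05,
  "treated_group": "noac",
  "exposure_sets": {
    "warfarin": {"codes": ["WARF"], "match_mode": "exact"},
    "noac": {"codes": ["NOAC_A", "NOAC_B", "NOAC_C"], "match_mode": "exact"}
  },
  "outcome_sets": {
    "stroke": {"codes": ["I63"], "match_mode": "prefix"}
  },
  "incident_exclusion_sets": {
    "stroke": {"codes": ["I63", "G45"], "match_mode": "prefix"}
  },
  "code_sets": {
    "af": {"codes": ["I48"], "match_mode": "prefix"}
  },
  "criteria": [
    {"label": "AF diagnosis before index", "kind": "require_diagnosis",
     "code_set": "af", "window": [-3650, 0]},
    {"label": "aged at least 20 at index", "kind": "age_at_least", "min_age": 20}
  ],
  "covariates": [
    {"name": "hypertension", "source": "diagnosis_flag",
     "code_set": {"codes": ["DX_HYPERTENSION"], "match_mode": "exact"}},
    {"name": "diabetes", "source": "diagnosis_flag",
     "code_set": {"codes": ["DX_DIABETES"], "match_mode": "exact"}},
    {"name": "heart_failure", "source": "diagnosis_flag",
     "code_set": {"codes": ["DX_HEART_FAILURE"], "match_mode": "exact"}},
    {"name": "rx_antiplatelet", "source": "prescription_flag",
     "code_set": {"codes": ["RX_ANTIPLATELET"], "match_mode": "exact"}}
  ],
  "ps_covariates": ["age_years", "sex", "hypertension", "diabetes",
                    "heart_failure", "rx_antiplatelet"],
  "cox_covariates": ["age_years", "sex", "hypertension", "diabetes",
                     "heart_failure", "rx_antiplatelet"],
  "seed": 1
}
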