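# non-standard-evaluation column names used inside data.table expressions
utils::globalVariables(c(
  ".", ".I", ".N", ".SD", "patient_id", "date", "interval", "n_visits",
  "provider_role", "duration_minutes", "code", "code_system", "egfr", "yr",
  "i.v", "age", "has_index", "flagged", "tr", "observed", "expected", "oe",
  "n_patients", "term", "marker", "ci", "ci_low", "ci_high", "or",
  "predictor", "clinic_id", "procedure", "day", "gap", "row", "egfr_category",
  "birth_year", "ses_decile", "probability"
))
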