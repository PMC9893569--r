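{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "hcineq study report",
  "type": "object",
  "required": ["meta", "prevalence", "indices", "filter_log"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["seed", "variant", "ci_method", "config_hash", "package_version"]
    },
    "prevalence": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["wave", "outcome", "n_users", "n", "pct"]
      }
    },
    "indices": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["wave", "outcome", "region", "variant", "value",
                     "ci_low", "ci_high", "stars", "classification"]
      }
    },
    "indices_by_region": {
      "type": ["array", "null"]
    },
    "decompositions": {
      "type": ["object", "array", "null"]
    },
    "filter_log": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["filter", "rows_in", "rows_retained", "rows_excluded"]
      }
    }
  }
}
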