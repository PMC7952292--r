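{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "eqvalid full validation report",
  "type": "object",
  "required": [
    "feasibility",
    "redistribution",
    "ceiling",
    "informativity",
    "known_groups",
    "age_regressions",
    "convergent",
    "construct_validity",
    "meta"
  ],
  "properties": {
    "feasibility": { "type": "object" },
    "redistribution": { "type": "object" },
    "ceiling": { "type": "object" },
    "informativity": { "type": "object" },
    "known_groups": { "type": "object" },
    "age_regressions": { "type": "object" },
    "convergent": { "type": "object" },
    "construct_validity": { "type": "object" },
    "meta": {
      "type": "object",
      "required": ["n", "seed", "value_set_5L", "value_set_3L", "package_version"]
    }
  }
}
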