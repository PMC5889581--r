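{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dockzones exploded-view layout export",
  "type": "object",
  "required": ["grid", "configurations"],
  "properties": {
    "grid": {
      "type": "object",
      "required": ["step", "focal", "margin", "axis", "origin"],
      "properties": {
        "step": {"type": "number", "exclusiveMinimum": 0},
        "focal": {"type": "number", "exclusiveMinimum": 0},
        "margin": {"type": "number"},
        "axis": {"type": "array", "minItems": 3, "maxItems": 3},
        "origin": {"type": "array", "minItems": 3, "maxItems": 3}
      }
    },
    "configurations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["config_id", "paired_matrix", "reference_matrix",
                     "tube"],
        "properties": {
          "config_id": {"type": "string"},
          "paired_matrix": {"type": "array", "minItems": 16,
                            "maxItems": 16},
          "reference_matrix": {"type": "array", "minItems": 16,
                               "maxItems": 16},
          "tube": {
            "type": "object",
            "required": ["reference", "paired"],
            "properties": {
              "reference": {"type": "array", "minItems": 3, "maxItems": 3},
              "paired": {"type": "array", "minItems": 3, "maxItems": 3}
            }
          }
        }
      }
    }
  }
}
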