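{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "carecascade model configuration",
  "description": "Schema for carecascade YAML/JSON scenario configurations. Validation is performed by carecascade::load_config(); this document describes the accepted shape. Unknown keys are rejected.",
  "type": "object",
  "additionalProperties": false,
  "required": ["baseline_id", "scenarios"],
  "properties": {
    "currency_symbol": {"type": "string", "default": "$"},
    "baseline_id": {"type": "string", "minLength": 1},
    "scenarios": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["scenario_id", "population_size", "prevalence", "filters"],
        "properties": {
          "scenario_id": {"type": "string", "minLength": 1},
          "label": {"type": "string"},
          "population_size": {"type": "number", "exclusiveMinimum": 0},
          "prevalence": {"type": "number", "minimum": 0, "maximum": 1},
          "filters": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "additionalProperties": false,
              "required": ["name", "pass_rate", "unit_cost"],
              "properties": {
                "name": {"type": "string", "minLength": 1},
                "description": {"type": "string"},
                "pass_rate": {"type": "number", "minimum": 0, "maximum": 1},
                "unit_cost": {"type": "number", "minimum": 0}
              }
            }
          }
        }
      }
    }
  }
}
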