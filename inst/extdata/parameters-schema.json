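{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "htncea model configuration",
  "description": "Schema for the YAML configuration of the hypertension prevention cost-utility model. All monetary units USD; all rates per year.",
  "type": "object",
  "required": ["transition", "hazards", "costs", "utilities", "compliance", "efficacy", "economics"],
  "$defs": {
    "param": {
      "description": "A scalar parameter: either a bare number (point mass) or a map with base-case value, uncertainty distribution and provenance tag.",
      "oneOf": [
        {"type": "number"},
        {
          "type": "object",
          "properties": {
            "value": {"type": "number"},
            "dist": {
              "type": "object",
              "minProperties": 1,
              "maxProperties": 1,
              "properties": {
                "beta": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}, "minItems": 2, "maxItems": 2},
                "triangular": {"type": "array", "items": {"type": "number"}, "minItems": 3, "maxItems": 3},
                "point": {"type": "array", "items": {"type": "number"}, "minItems": 1, "maxItems": 1}
              },
              "additionalProperties": false
            },
            "source": {"type": "string", "enum": ["paper_table1", "paper_s24", "assumption", "config", "synthetic"]}
          },
          "anyOf": [{"required": ["value"]}, {"required": ["dist"]}],
          "additionalProperties": false
        }
      ]
    },
    "perState": {
      "type": "object",
      "required": ["normal", "pre_hypertension", "stage1", "stage2"],
      "additionalProperties": {"$ref": "#/$defs/param"}
    },
    "hazardBlock": {
      "type": "object",
      "required": ["normal", "pre_hypertension", "stage1", "stage2", "mortality_immediate", "mortality_yearly"],
      "additionalProperties": {"$ref": "#/$defs/param"}
    },
    "rule": {
      "type": "object",
      "required": ["states", "bundle", "compliance"],
      "properties": {
        "states": {"type": "array", "items": {"enum": ["normal", "pre_hypertension", "stage1", "stage2"]}},
        "groups": {"type": "array", "items": {"enum": ["low", "mid", "high"]}},
        "bundle": {"type": "array", "items": {"type": "string"}},
        "compliance": {"enum": ["lifestyle", "screening", "medication"]}
      }
    }
  },
  "properties": {
    "meta": {"type": "object"},
    "transition": {
      "type": "object",
      "required": ["p_normal_to_pre", "p_pre_to_stage1", "p_stage1_to_stage2", "p_pre_to_normal"],
      "additionalProperties": {"$ref": "#/$defs/param"}
    },
    "hazards": {
      "type": "object",
      "required": ["mi", "stroke", "esrd"],
      "properties": {
        "mi": {"$ref": "#/$defs/hazardBlock"},
        "stroke": {"$ref": "#/$defs/hazardBlock"},
        "esrd": {"$ref": "#/$defs/hazardBlock"}
      }
    },
    "costs": {
      "type": "object",
      "required": ["mi_admission", "mi_visit", "stroke_admission", "stroke_visit", "esrd_annual", "hypertension_admission", "hypertension_visit", "lifestyle_low", "lifestyle_mid", "lifestyle_full", "advanced_checkup", "regular_checkup", "screening_low_awareness", "terminal_care", "prophylactic_drug"],
      "additionalProperties": {"$ref": "#/$defs/param"}
    },
    "utilities": {
      "type": "object",
      "required": ["state", "complication"],
      "properties": {
        "state": {"$ref": "#/$defs/perState"},
        "complication": {
          "type": "object",
          "required": ["mi", "stroke", "esrd"],
          "additionalProperties": {"$ref": "#/$defs/param"}
        },
        "combination_rule": {"enum": ["product", "minimum"]}
      }
    },
    "compliance": {
      "type": "object",
      "required": ["lifestyle", "screening", "medication"],
      "additionalProperties": {"$ref": "#/$defs/param"}
    },
    "efficacy": {
      "type": "object",
      "required": ["sbp_reduction"],
      "properties": {
        "sbp_reduction": {"$ref": "#/$defs/perState"},
        "dbp_reduction": {"$ref": "#/$defs/perState"}
      }
    },
    "economics": {
      "type": "object",
      "required": ["discount_rate", "horizon_years", "initial_state_distribution"],
      "properties": {
        "discount_rate": {"$ref": "#/$defs/param"},
        "horizon_years": {"type": "integer", "minimum": 1},
        "initial_state_distribution": {"$ref": "#/$defs/perState"}
      }
    },
    "risk_model": {
      "type": "object",
      "properties": {
        "weights": {"type": "object", "additionalProperties": {"type": "number"}},
        "intercept": {"type": "number"},
        "group_scores": {"type": "object"},
        "group_weights": {"type": "object"},
        "modify_regression": {"type": "boolean"}
      }
    },
    "state_costs": {"type": "object"},
    "strategies": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["rules"],
        "properties": {"rules": {"type": "array", "items": {"$ref": "#/$defs/rule"}}}
      }
    }
  }
}
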