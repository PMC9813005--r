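{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "studychar article record",
  "type": "object",
  "required": ["id", "features", "values"],
  "properties": {
    "id": {"type": "string"},
    "features": {
      "type": "object",
      "properties": {
        "methods": {"type": "array", "items": {"type": "string"}},
        "alpha": {
          "type": "object",
          "properties": {
            "nominal": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1}},
            "corrected": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1}},
            "from_ci": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1}},
            "max_alpha": {"type": ["number", "null"]},
            "min_alpha": {"type": ["number", "null"]}
          }
        },
        "power": {
          "type": "object",
          "properties": {
            "values": {"type": "array", "items": {"type": "number", "minimum": 0, "maximum": 1}},
            "beta_converted": {"type": "array", "items": {"type": "number", "minimum": 0, "maximum": 1}}
          }
        },
        "correction": {
          "type": "object",
          "properties": {
            "authors": {"type": "array", "items": {"type": "string"}},
            "procedures": {"type": "array", "items": {"type": "string"}}
          }
        },
        "interaction": {
          "type": "object",
          "properties": {
            "interaction": {"type": "boolean"},
            "mediator": {"type": "boolean"},
            "moderator": {"type": "boolean"},
            "any": {"type": "boolean"}
          }
        },
        "direction": {"enum": ["none", "one_sided", "two_sided", "both"]},
        "outlier_sd": {"type": "array", "items": {"type": "number", "minimum": 1, "maximum": 10}},
        "assumptions": {"type": "array", "items": {"type": "string"}},
        "software": {
          "type": "object",
          "properties": {
            "software": {"type": "array", "items": {"type": "string"}},
            "user_added": {"type": "array", "items": {"type": "string"}}
          }
        },
        "n_studies": {"type": "integer", "minimum": 1}
      }
    },
    "values": {
      "type": "object",
      "additionalProperties": {"type": "array", "items": {"type": "string"}}
    },
    "errors": {"type": "object"}
  }
}
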