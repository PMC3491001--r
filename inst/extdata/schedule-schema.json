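{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "smokesim policy schedule config",
  "description": "Per-year policy levels. Fields omitted from a year block carry forward from the previous block.",
  "type": "object",
  "required": ["base_year", "years"],
  "properties": {
    "base_year": {"type": "integer"},
    "years": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["year"],
        "properties": {
          "year": {"type": "integer"},
          "price_index": {"type": "number", "exclusiveMinimum": 0},
          "smokefree": {
            "type": "object",
            "properties": {
              "worksite": {"type": "number", "minimum": 0, "maximum": 1},
              "restaurant": {"type": "number", "minimum": 0, "maximum": 1},
              "bar": {"type": "number", "minimum": 0, "maximum": 1},
              "other": {"type": "number", "minimum": 0, "maximum": 1},
              "enforcement": {"type": "number", "minimum": 0, "maximum": 1}
            }
          },
          "media": {"enum": ["none", "low", "moderate", "high"]},
          "marketing": {
            "type": "object",
            "properties": {
              "level": {"enum": ["none", "weak", "total", "comprehensive"]},
              "enforcement": {"type": "number", "minimum": 0, "maximum": 1}
            }
          },
          "warnings": {"enum": ["none", "weak", "strong"]},
          "cessation_treatment": {"type": "number", "minimum": 0, "maximum": 1},
          "youth_access": {"enum": ["none", "low", "moderate", "strong"]}
        }
      }
    }
  }
}
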