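{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "cstack-1",
  "title": "Contour stack (cstack-1 dialect)",
  "type": "object",
  "required": ["structure", "gap_mm", "slices"],
  "properties": {
    "version": {"const": "cstack-1"},
    "structure": {"type": "string"},
    "gap_mm": {"type": "number", "exclusiveMinimum": 0},
    "slices": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["index", "z_mm", "contours"],
        "properties": {
          "index": {"type": "integer", "minimum": 0},
          "z_mm": {"type": "number"},
          "contours": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["label", "points"],
              "properties": {
                "label": {"type": "string"},
                "points": {
                  "type": "array",
                  "minItems": 3,
                  "items": {
                    "type": "array",
                    "minItems": 2,
                    "maxItems": 2,
                    "items": {"type": "number"}
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
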