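{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Spine corner-keypoint annotations",
  "type": "object",
  "required": ["annotations"],
  "properties": {
    "annotations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["subject_id", "vertebrae"],
        "properties": {
          "subject_id": {"type": "string"},
          "image_size": {
            "oneOf": [
              {"type": "null"},
              {"type": "array", "items": {"type": "number", "minimum": 0},
               "minItems": 2, "maxItems": 2}
            ],
            "description": "[width, height] in pixels"
          },
          "pixel_spacing": {
            "oneOf": [{"type": "null"}, {"type": "number", "exclusiveMinimum": 0}],
            "description": "mm per pixel (metadata only)"
          },
          "vertebrae": {
            "type": "array",
            "minItems": 4,
            "description": "cranial to caudal order; centroid y strictly increasing",
            "items": {
              "type": "object",
              "required": ["label", "corners"],
              "properties": {
                "label": {
                  "oneOf": [
                    {"type": "string", "pattern": "^(T(1[0-2]|[1-9])|L[1-5])$"},
                    {"type": "integer", "minimum": 0}
                  ]
                },
                "corners": {
                  "type": "array",
                  "minItems": 4,
                  "maxItems": 4,
                  "description": "pixel [x, y]; order upper-left, upper-right, lower-right, lower-left; origin top-left, y increases caudally",
                  "items": {
                    "type": "array",
                    "items": {"type": "number", "minimum": 0},
                    "minItems": 2,
                    "maxItems": 2
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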