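{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "handmetry analysis report",
  "type": "object",
  "required": ["schema_version", "tool_version", "config_hash", "timestamp",
               "capture_validation"],
  "properties": {
    "schema_version": {"type": "string"},
    "tool_version": {"type": "string"},
    "config_hash": {"type": "string"},
    "source": {"type": "string"},
    "patient_id": {"type": "string"},
    "side": {"type": ["string", "null"], "enum": ["left", "right", null]},
    "timestamp": {"type": "string"},
    "capture_validation": {
      "type": "object",
      "required": ["checks", "valid"],
      "properties": {
        "checks": {
          "type": "object",
          "required": ["four_corners_visible", "hand_within_edges",
                       "fingers_spread", "background_darker_uncluttered"],
          "additionalProperties": {"type": "boolean"}
        },
        "violations": {"type": "array", "items": {"type": "string"}},
        "valid": {"type": "boolean"}
      }
    },
    "calibration": {
      "type": ["object", "null"],
      "properties": {
        "scale_mm_per_px": {"type": "number"},
        "aspect_mismatch": {"type": "number"},
        "corner_confidence": {"type": "array", "items": {"type": "number"}}
      }
    },
    "measurements": {
      "type": ["object", "null"],
      "properties": {
        "fingers": {"type": "object"},
        "palm_width_mm": {"type": ["number", "null"]},
        "span_mm": {"type": "number"},
        "handedness": {"type": "string"},
        "scale_mm_per_px": {"type": "number"}
      }
    },
    "change": {"type": ["object", "null"]},
    "failure": {"type": ["object", "null"]}
  }
}
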